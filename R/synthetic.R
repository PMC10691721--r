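#' @title Synthetic EGG generator
#' @description Seeded generator of EGG-like recordings: a gastric slow wave
#'   (sinusoid plus a weighted second harmonic with Ornstein-Uhlenbeck
#'   frequency jitter), pink background noise, physiologically implausible
#'   spikes, slow motion artifacts, a biphasic VNS pulse train, and
#'   condition-dependent effects (amplitude scaling under 10 Hz stimulation;
#'   dominant-frequency shift and extra irregularity under 30 Hz).
#' @name synthetic_egg
NULL

# run expr with a private RNG stream; never disturbs the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# deterministic sub-seed derivation, kept below 2^31
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Generator parameters for synthetic EGG recordings
#'
#' Defaults define the simulated study conditions: a 10 cpm ferret gastric
#' slow wave of 200 uV with moderate frequency jitter and pink noise, sparse
#' implausible spikes and slow motion artifacts, and VNS effects (a strong
#' amplitude scaling for 10 Hz stimulation; a -2 cpm dominant-frequency shift
#' plus extra irregularity for 30 Hz).
#'
#' @param slow_wave_freq_cpm slow-wave fundamental, cycles per minute.
#' @param slow_wave_amp_uv slow-wave amplitude, uV.
#' @param harmonic_weight relative weight of the second harmonic, in \[0, 1\].
#' @param freq_jitter_sd_cpm stationary SD of the Ornstein-Uhlenbeck
#'   instantaneous-frequency jitter, cpm.
#' @param pink_noise_sd_uv SD of the 1/f background noise, uV.
#' @param spike_rate_per_min Poisson rate of implausible spikes
#'   (|amplitude| > 1e8 uV) per minute.
#' @param motion_artifact_rate_per_min Poisson rate of slow motion-artifact
#'   bumps (|amplitude| in 3000-10000 uV) per minute.
#' @param vns_pulse_freq_hz stimulation pulse frequency, one of 0, 10, 30
#'   (0 = no stimulation).
#' @param vns_pulse_amp_uv amplitude of each biphasic pulse, uV.
#' @param amp_effect multiplicative slow-wave amplitude scaling applied only
#'   when `condition = "vns"` and `vns_pulse_freq_hz = 10`.
#' @param freq_shift_cpm additive dominant-frequency shift applied only when
#'   `condition = "vns"` and `vns_pulse_freq_hz = 30`.
#' @param complexity_effect extra irregularity (additional frequency jitter,
#'   cpm, plus in-band broadband noise) applied only when `condition = "vns"`
#'   and `vns_pulse_freq_hz = 30`.
#' @param seed integer seed; identical (params, seed) give bit-identical
#'   output.
#' @return an object of class `egg_generator_params`.
#' @export
generator_params <- function(slow_wave_freq_cpm = 10,
                             slow_wave_amp_uv = 200,
                             harmonic_weight = 0.3,
                             freq_jitter_sd_cpm = 0.5,
                             pink_noise_sd_uv = 50,
                             spike_rate_per_min = 0.2,
                             motion_artifact_rate_per_min = 0.2,
                             vns_pulse_freq_hz = 0,
                             vns_pulse_amp_uv = 5000,
                             amp_effect = 1.5,
                             freq_shift_cpm = -2,
                             complexity_effect = 1.5,
                             seed = 1L) {
  stopifnot(
    slow_wave_freq_cpm > 0, slow_wave_amp_uv >= 0,
    harmonic_weight >= 0, harmonic_weight <= 1,
    freq_jitter_sd_cpm >= 0, pink_noise_sd_uv >= 0,
    spike_rate_per_min >= 0, motion_artifact_rate_per_min >= 0,
    vns_pulse_freq_hz %in% c(0, 10, 30),
    vns_pulse_amp_uv >= 0, amp_effect >= 0, complexity_effect >= 0
  )
  structure(as.list(environment()), class = "egg_generator_params")
}

#' Study design for a simulated VNS experiment
#'
#' Each (subject, stimulation frequency) session yields exactly one baseline
#' and one VNS recording, mirroring a within-subject design of 10-minute
#' baseline followed by 10 minutes of stimulation.
#'
#' @param n_subjects number of subjects (default 7).
#' @param stim_freqs_hz stimulation frequencies tested, subset of c(10, 30).
#' @param segment_duration_s duration of each recording, seconds.
#' @param fs_hz sampling rate, Hz.
#' @param seed integer master seed.
#' @return an object of class `egg_study_design`.
#' @export
study_design <- function(n_subjects = 7L,
                         stim_freqs_hz = c(10, 30),
                         segment_duration_s = 600,
                         fs_hz = 2000,
                         seed = 1L) {
  if (length(stim_freqs_hz) == 0)
    stop("stim_freqs_hz must contain at least one of 10, 30", call. = FALSE)
  stopifnot(n_subjects >= 1, all(stim_freqs_hz %in% c(10, 30)),
            segment_duration_s > 0, fs_hz > 0)
  structure(as.list(environment()), class = "egg_study_design")
}

#' Construct a recording object
#'
#' @param samples numeric vector of amplitudes, uV.
#' @param fs_hz sampling rate, Hz.
#' @param subject_id,session_id,condition,stim_freq_hz,channel_label metadata.
#' @return an object of class `egg_recording`.
#' @export
egg_recording <- function(samples, fs_hz,
                          subject_id = "s1", session_id = "sess1",
                          condition = c("baseline", "vns"),
                          stim_freq_hz = 0, channel_label = "gastric") {
  condition <- match.arg(condition)
  stopifnot(fs_hz > 0, stim_freq_hz %in% c(0, 10, 30))
  if (condition == "baseline" && stim_freq_hz != 0)
    stop("baseline recordings must have stim_freq_hz = 0", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs_hz = fs_hz,
         subject_id = subject_id, session_id = session_id,
         condition = condition, stim_freq_hz = stim_freq_hz,
         channel_label = channel_label),
    class = "egg_recording"
  )
}

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf(
    "<egg_recording> %s/%s %s (stim %g Hz): %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$session_id, x$condition, x$stim_freq_hz,
    length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  invisible(x)
}

# pink (1/f power) noise via spectral shaping of white noise, unit SD.
# The 1/f shaping is cornered (flat) below corner_hz so the divergence near
# DC cannot swamp the slow-wave line inside the analysis passband.
.pink_noise <- function(n, fs_hz, corner_hz = 0.05) {
  if (n < 2L) return(rnorm(n))
  w <- .fft_any(as.complex(rnorm(n)))
  k <- 0:(n - 1)
  f_idx <- pmax(pmin(k, n - k), 1)    # mirror-symmetric |frequency| index
  f_hz <- pmax(f_idx * fs_hz / n, corner_hz)
  shaped <- Re(.fft_any(w / sqrt(f_hz), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  s <- stats::sd(shaped)
  if (s > 0) shaped / s else shaped
}

# Ornstein-Uhlenbeck process with stationary SD `sd` and correlation time
# `tau_s`, sampled at fs; AR(1) exact discretization
.ou_process <- function(n, sd, tau_s, fs_hz) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  a <- exp(-1 / (tau_s * fs_hz))
  innov <- rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sd)       # start in the stationary distribution
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Generate one synthetic EGG recording
#'
#' @param condition "baseline" or "vns".
#' @param params a [generator_params()] object; `vns_pulse_freq_hz` must be
#'   0 iff `condition = "baseline"`.
#' @param duration_s recording duration, seconds.
#' @param fs_hz sampling rate, Hz.
#' @param subject_id,session_id metadata carried on the recording.
#' @return an [egg_recording()].
#' @details Component RNG streams (jitter, noise, spikes, motion artifacts)
#'   are seeded independently from `params$seed`, so e.g. the spike draw can
#'   be reproduced in isolation.
#' @export
generate_recording <- function(condition = c("baseline", "vns"),
                               params = generator_params(),
                               duration_s = 600, fs_hz = 2000,
                               subject_id = "s1", session_id = "sess1") {
  condition <- match.arg(condition)
  if (!(duration_s > 0)) stop("duration_s must be > 0", call. = FALSE)
  if (!(fs_hz > 0)) stop("fs_hz must be > 0", call. = FALSE)
  if ((condition == "baseline") != (params$vns_pulse_freq_hz == 0))
    stop("vns_pulse_freq_hz must be 0 iff condition is baseline",
         call. = FALSE)

  n <- round(duration_s * fs_hz)
  dur_min <- duration_s / 60
  is_vns10 <- condition == "vns" && params$vns_pulse_freq_hz == 10
  is_vns30 <- condition == "vns" && params$vns_pulse_freq_hz == 30

  f0_cpm <- params$slow_wave_freq_cpm + if (is_vns30) params$freq_shift_cpm else 0
  amp <- params$slow_wave_amp_uv * if (is_vns10) params$amp_effect else 1
  jitter_sd <- params$freq_jitter_sd_cpm +
    if (is_vns30) params$complexity_effect else 0

  # slow wave: integrated instantaneous frequency (fundamental + OU jitter)
  jitter_cpm <- .with_seed(.sub_seed(params$seed, 1),
                           .ou_process(n, jitter_sd, tau_s = 10, fs_hz = fs_hz))
  inst_freq_hz <- pmax(f0_cpm + jitter_cpm, 0.5) / 60
  phase <- 2 * pi * cumsum(inst_freq_hz) / fs_hz
  x <- amp * (sin(phase) + params$harmonic_weight * sin(2 * phase))

  if (params$pink_noise_sd_uv > 0) {
    x <- x + params$pink_noise_sd_uv *
      .with_seed(.sub_seed(params$seed, 2), .pink_noise(n, fs_hz))
  }

  if (is_vns30 && params$complexity_effect > 0) {
    # broadband in-band irregularity accompanying the frequency effect
    x <- x + 0.1 * params$complexity_effect * params$slow_wave_amp_uv *
      .with_seed(.sub_seed(params$seed, 3), .pink_noise(n, fs_hz))
  }

  # implausible spikes: single samples, |amp| uniform in [2e8, 1e9] uV
  x <- .with_seed(.sub_seed(params$seed, 4), {
    k <- stats::rpois(1, params$spike_rate_per_min * dur_min)
    if (k > 0) {
      idx <- sample.int(n, min(k, n))
      x[idx] <- x[idx] + sample(c(-1, 1), length(idx), replace = TRUE) *
        stats::runif(length(idx), 2e8, 1e9)
    }
    x
  })

  # motion artifacts: slow half-sine bumps (5-20 s) within the passband,
  # |amp| uniform in [3000, 10000] uV so the 2000 uV clamp is exercised
  x <- .with_seed(.sub_seed(params$seed, 5), {
    k <- stats::rpois(1, params$motion_artifact_rate_per_min * dur_min)
    if (k > 0) {
      for (i in seq_len(k)) {
        len <- round(stats::runif(1, 5, 20) * fs_hz)
        start <- sample.int(max(n - len, 1L), 1)
        stop_ <- min(start + len - 1L, n)
        seg <- seq_len(stop_ - start + 1L)
        bump <- sin(pi * (seg - 1) / (length(seg) - 1))
        x[start:stop_] <- x[start:stop_] +
          sample(c(-1, 1), 1) * stats::runif(1, 3000, 10000) * bump
      }
    }
    x
  })

  # biphasic pulse train: one positive and one adjacent negative sample per
  # pulse (0.1 ms pulse width is sub-sample at 2 kHz)
  if (condition == "vns" && params$vns_pulse_amp_uv > 0) {
    step <- fs_hz / params$vns_pulse_freq_hz
    pos <- round(seq(1, n - 1, by = step))
    pos <- pos[pos >= 1 & pos + 1 <= n]
    x[pos] <- x[pos] + params$vns_pulse_amp_uv
    x[pos + 1] <- x[pos + 1] - params$vns_pulse_amp_uv
  }

  egg_recording(x, fs_hz, subject_id = subject_id, session_id = session_id,
                condition = condition,
                stim_freq_hz = if (condition == "vns") params$vns_pulse_freq_hz else 0)
}

#' Generate a full simulated study
#'
#' Produces `2 * n_subjects * length(stim_freqs_hz)` recordings: one baseline
#' and one VNS recording per (subject, stimulation frequency) session.
#'
#' @param design a [study_design()].
#' @param params a [generator_params()] template; its `vns_pulse_freq_hz` and
#'   `seed` are overridden per recording (seeds derived from `design$seed`).
#' @return a list of [egg_recording()] objects.
#' @export
generate_study <- function(design = study_design(),
                           params = generator_params()) {
  recs <- list()
  i <- 0L
  for (subj in seq_len(design$n_subjects)) {
    for (f in design$stim_freqs_hz) {
      session <- sprintf("s%02d_f%02d", subj, as.integer(f))
      for (cond in c("baseline", "vns")) {
        i <- i + 1L
        p <- params
        p$vns_pulse_freq_hz <- if (cond == "vns") f else 0
        p$seed <- .sub_seed(design$seed, i * 17L)
        recs[[i]] <- generate_recording(
          cond, p, duration_s = design$segment_duration_s,
          fs_hz = design$fs_hz,
          subject_id = sprintf("subj%02d", subj), session_id = session)
      }
    }
  }
  recs
}
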