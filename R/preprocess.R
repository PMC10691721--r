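#' @title Artifact-robust EGG pre-processing
#' @description The pre-processing chain: excision of physiologically
#'   implausible spikes, index-blocked DCT band-pass filtering, clamping of
#'   out-of-range amplitudes to the signal mean, decimation, and overlapping
#'   windowing with per-window removed-sample bookkeeping.
#' @name preprocessing
NULL

#' Pre-processing configuration
#'
#' Defaults follow the analysis protocol: spikes above 1e8 uV are excised,
#' the passband is 0.01-0.5 Hz (0.6-30 cpm), amplitudes above 2000 uV are
#' substituted by the signal mean, windows are 60 s with 20 s overlap, and
#' windows losing 30% or more of their raw samples are discarded.
#'
#' @param spike_threshold_uv stage-1 excision threshold, uV.
#' @param band_lo_hz,band_hi_hz passband edges, Hz.
#' @param clamp_threshold_uv stage-3 substitution threshold, uV.
#' @param window_s,overlap_s window length and overlap, seconds.
#' @param max_removed_pct windows with `removed_pct >= max_removed_pct` are
#'   dropped (strict less-than keeps a window).
#' @param decimate_to_hz target rate after band-passing; must divide the
#'   recording rate. 4 Hz is 8x the 0.5 Hz passband edge, so nothing in-band
#'   is lost while O(N^2) entropy estimators stay tractable.
#' @return an object of class `egg_preprocess_config`.
#' @export
preprocess_config <- function(spike_threshold_uv = 1e8,
                              band_lo_hz = 0.01, band_hi_hz = 0.5,
                              clamp_threshold_uv = 2000,
                              window_s = 60, overlap_s = 20,
                              max_removed_pct = 30,
                              decimate_to_hz = 4) {
  stopifnot(spike_threshold_uv > 0, band_lo_hz >= 0,
            band_lo_hz < band_hi_hz, clamp_threshold_uv > 0,
            window_s > 0, overlap_s >= 0, overlap_s < window_s,
            max_removed_pct >= 0, decimate_to_hz > 0)
  structure(as.list(environment()), class = "egg_preprocess_config")
}

#' Excise physiologically implausible spikes
#'
#' Deletes every sample with `|x| > threshold_uv` (the array shortens); the
#' count of deleted samples feeds the removed-pct bookkeeping.
#'
#' @param samples numeric vector, uV.
#' @param threshold_uv excision threshold, uV.
#' @return list with `samples` (shortened vector), `excised_count`, and
#'   `excised_idx` (positions in the input).
#' @export
excise_extreme <- function(samples, threshold_uv = 1e8) {
  if (!(threshold_uv > 0)) stop("threshold_uv must be > 0", call. = FALSE)
  if (length(samples) == 0)
    return(list(samples = numeric(0), excised_count = 0L,
                excised_idx = integer(0)))
  bad <- which(abs(samples) > threshold_uv)
  list(samples = if (length(bad)) samples[-bad] else samples,
       excised_count = length(bad), excised_idx = bad)
}

#' Index-blocked DCT band-pass filter
#'
#' Takes the orthonormal DCT of the whole signal, zeroes every coefficient
#' whose index frequency `k * fs / (2N)` falls outside `[lo_hz, hi_hz]`, and
#' inverts. Zero phase, output length equals input length.
#'
#' @param samples numeric vector, uV.
#' @param fs_hz sampling rate, Hz.
#' @param lo_hz,hi_hz passband edges, Hz; `0 <= lo_hz < hi_hz <= fs_hz / 2`.
#' @return filtered numeric vector.
#' @export
ibdctfm_bandpass <- function(samples, fs_hz, lo_hz = 0.01, hi_hz = 0.5) {
  if (!(lo_hz >= 0 && lo_hz < hi_hz && hi_hz <= fs_hz / 2))
    stop("invalid band: need 0 <= lo_hz < hi_hz <= fs_hz/2", call. = FALSE)
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  coef <- dct_ii(samples)
  freq <- (0:(n - 1)) * fs_hz / (2 * n)
  coef[freq < lo_hz | freq > hi_hz] <- 0
  dct_iii(coef)
}

#' Clamp out-of-range amplitudes to the signal mean
#'
#' Samples with `|x| > threshold_uv` are replaced by the mean of the
#' pre-substitution array (single pass); length is unchanged.
#'
#' @param samples numeric vector, uV.
#' @param threshold_uv substitution threshold, uV.
#' @return list with `samples`, `substituted_count`, `substituted_idx`.
#' @export
clamp_substitute <- function(samples, threshold_uv = 2000) {
  if (!(threshold_uv > 0)) stop("threshold_uv must be > 0", call. = FALSE)
  if (length(samples) == 0)
    return(list(samples = numeric(0), substituted_count = 0L,
                substituted_idx = integer(0)))
  bad <- which(abs(samples) > threshold_uv)
  if (length(bad)) samples[bad] <- mean(samples)
  list(samples = samples, substituted_count = length(bad),
       substituted_idx = bad)
}

#' Percentage of removed signal
#'
#' `removed_pct = 100 * (excised + substituted) / raw_length`; windows at or
#' above the 30% default cutoff are excluded from modelling.
#'
#' @param excised,substituted sample counts from the two thresholding stages.
#' @param raw_length number of raw samples the counts refer to.
#' @return percentage in \[0, 100\].
#' @export
compute_removed_pct <- function(excised, substituted, raw_length) {
  if (!(raw_length > 0)) stop("raw_length must be > 0", call. = FALSE)
  stopifnot(excised >= 0, substituted >= 0,
            excised + substituted <= raw_length)
  100 * (excised + substituted) / raw_length
}

#' Decimate a band-limited signal by sample picking
#'
#' Retains every k-th sample, `k = fs_hz / target_hz` (must be an integer).
#' Intended for signals already band-passed well below `target_hz / 2`.
#'
#' @param samples numeric vector.
#' @param fs_hz current sampling rate, Hz.
#' @param target_hz target rate, Hz.
#' @return list with `samples` and `fs_hz` (the new rate).
#' @export
decimate_signal <- function(samples, fs_hz, target_hz) {
  if (!(target_hz > 0 && target_hz <= fs_hz))
    stop("target_hz must be in (0, fs_hz]", call. = FALSE)
  k <- fs_hz / target_hz
  if (abs(k - round(k)) > 1e-9)
    stop("fs_hz / target_hz must be an integer", call. = FALSE)
  k <- as.integer(round(k))
  list(samples = samples[seq(1L, length(samples), by = k)],
       fs_hz = target_hz)
}

#' Segment a signal into overlapping windows
#'
#' Windows start at multiples of `window_s - overlap_s`; a trailing partial
#' window is discarded.
#'
#' @param samples numeric vector.
#' @param fs_hz sampling rate, Hz.
#' @param window_s,overlap_s window length and overlap, seconds.
#' @return list of lists, each with `samples` and `start_time_s`. Empty (with
#'   a warning) if the signal is shorter than one window.
#' @export
segment_windows <- function(samples, fs_hz, window_s = 60, overlap_s = 20) {
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s)
  step_s <- window_s - overlap_s
  wlen <- round(window_s * fs_hz)
  slen <- round(step_s * fs_hz)
  n <- length(samples)
  if (n < wlen) {
    warning("signal shorter than one window; returning no windows")
    return(list())
  }
  n_win <- floor((n - wlen) / slen) + 1L
  lapply(seq_len(n_win) - 1L, function(i) {
    start <- i * slen
    list(samples = samples[(start + 1L):(start + wlen)],
         start_time_s = start / fs_hz)
  })
}

#' Run the full pre-processing chain on a recording
#'
#' Applies, in fixed order: spike excision, index-blocked DCT band-pass,
#' mean-substitution clamping, decimation, and overlapping windowing. Each
#' window carries a `removed_pct` computed from the excised and substituted
#' samples whose original positions fall inside the window's time span;
#' windows with `removed_pct >= max_removed_pct` are dropped.
#'
#' @param recording an [egg_recording()].
#' @param config an [preprocess_config()].
#' @return list of `egg_window` objects (samples, fs_hz, start_time_s,
#'   removed_pct, label, stim_freq_hz, subject_id, session_id), with
#'   attributes `excised_count`, `substituted_count`, `n_windows_raw`,
#'   `n_windows_dropped`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "egg_recording"))
  fs <- recording$fs_hz
  raw <- recording$samples
  n0 <- length(raw)

  st1 <- excise_extreme(raw, config$spike_threshold_uv)
  # original raw positions of the samples surviving stage 1
  orig_idx <- if (st1$excised_count > 0) {
    seq_len(n0)[-st1$excised_idx]
  } else seq_len(n0)

  filt <- ibdctfm_bandpass(st1$samples, fs, config$band_lo_hz,
                           config$band_hi_hz)
  st3 <- clamp_substitute(filt, config$clamp_threshold_uv)
  sub_orig_idx <- orig_idx[st3$substituted_idx]

  dec <- decimate_signal(st3$samples, fs, config$decimate_to_hz)
  wins <- segment_windows(dec$samples, dec$fs_hz,
                          config$window_s, config$overlap_s)

  raw_per_window <- round(config$window_s * fs)
  exc_t <- (st1$excised_idx - 1) / fs       # original-time positions
  sub_t <- (sub_orig_idx - 1) / fs

  out <- list()
  dropped <- 0L
  for (w in wins) {
    t0 <- w$start_time_s
    t1 <- t0 + config$window_s
    exc_in <- sum(exc_t >= t0 & exc_t < t1)
    sub_in <- sum(sub_t >= t0 & sub_t < t1)
    rp <- compute_removed_pct(exc_in, sub_in, raw_per_window)
    if (rp >= config$max_removed_pct) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(samples = w$samples, fs_hz = dec$fs_hz,
           start_time_s = w$start_time_s, removed_pct = rp,
           label = recording$condition,
           stim_freq_hz = recording$stim_freq_hz,
           subject_id = recording$subject_id,
           session_id = recording$session_id),
      class = "egg_window")
  }
  attr(out, "excised_count") <- st1$excised_count
  attr(out, "substituted_count") <- st3$substituted_count
  attr(out, "n_windows_raw") <- length(wins)
  attr(out, "n_windows_dropped") <- dropped
  out
}
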