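#' @title Frequency-domain window features
#' @description Welch power spectral density on a cycles-per-minute grid and
#'   the spectral descriptors derived from it: dominant frequency and power,
#'   PMMP, spectral entropy, gastric band powers, crest factor, median and
#'   mean power frequency.
#' @name freq_features
NULL

#' Welch power spectral density of one window
#'
#' Single-segment Welch estimate: the whole window is Hann-tapered,
#' mean-detrended and zero-padded so the frequency grid spacing equals
#' `resolution_cpm` (the native resolution of a 60 s window is 1 cpm, so the
#' 0.1 cpm grid is obtained by padding). One-sided density normalized so
#' that `sum(power) * df` approximates the signal variance.
#'
#' @param x numeric window.
#' @param fs_hz sampling rate, Hz.
#' @param resolution_cpm desired grid spacing in cycles/minute (default 0.1).
#' @return object of class `egg_psd`: list with `freqs_cpm`, `power`
#'   (uV^2/cpm), `resolution_cpm`.
#' @export
welch_psd <- function(x, fs_hz, resolution_cpm = 0.1) {
  n <- length(x)
  stopifnot(n >= 2, fs_hz > 0, resolution_cpm > 0)
  df_hz <- resolution_cpm / 60
  nfft <- round(fs_hz / df_hz)
  if (nfft < n) {
    warning("requested resolution coarser than native; no padding applied")
    nfft <- n
  }
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))  # symmetric Hann
  xt <- (x - mean(x)) * w
  spec <- abs(stats::fft(c(xt, rep(0, nfft - n))))^2 / (fs_hz * sum(w^2))
  n_keep <- floor(nfft / 2) + 1L
  power_hz <- spec[1:n_keep]
  power_hz[2:(n_keep - 1L)] <- 2 * power_hz[2:(n_keep - 1L)]  # one-sided
  freqs_cpm <- (0:(n_keep - 1L)) * (fs_hz / nfft) * 60
  structure(
    list(freqs_cpm = freqs_cpm, power = power_hz / 60,  # uV^2/cpm
         resolution_cpm = fs_hz / nfft * 60),
    class = "egg_psd")
}

# restrict a PSD to a cpm band (inclusive edges)
.psd_band <- function(psd, band_cpm) {
  keep <- psd$freqs_cpm >= band_cpm[1] & psd$freqs_cpm <= band_cpm[2]
  if (!any(keep)) stop("no PSD bins inside the requested band", call. = FALSE)
  list(freqs = psd$freqs_cpm[keep], power = psd$power[keep])
}

#' Dominant frequency and dominant power
#'
#' `DF` is the frequency of the maximum-power bin within the search band,
#' `DP` that bin's power. Ties resolve to the lowest frequency.
#'
#' @param psd an [welch_psd()] estimate.
#' @param df_band_cpm search band, cpm (default 0.6-30).
#' @return named list with `df` (cpm) and `dp` (uV^2/cpm).
#' @export
dominant_freq_power <- function(psd, df_band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, df_band_cpm)
  i <- which.max(b$power)              # which.max: first (lowest-f) maximum
  list(df = b$freqs[i], dp = b$power[i])
}

#' Percentage of PSD bins exceeding a quarter of the dominant power
#'
#' `100 * #\{bins with power > DP/4\} / #\{bins in band\}` (strict
#' inequality), over the dominant-frequency search band.
#'
#' @inheritParams dominant_freq_power
#' @return percentage in (0, 100\].
#' @export
pmmp <- function(psd, df_band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, df_band_cpm)
  dp <- max(b$power)
  100 * sum(b$power > dp / 4) / length(b$power)
}

#' Spectral entropy
#'
#' Shannon entropy of the power distribution over the passband, normalized
#' by `log(#bins)` to \[0, 1\].
#'
#' @inheritParams dominant_freq_power
#' @param band_cpm passband over which the PSD is normalized.
#' @return value in \[0, 1\].
#' @export
spectral_entropy <- function(psd, band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, band_cpm)
  tot <- sum(b$power)
  if (!(tot > 0)) stop("zero total power in band", call. = FALSE)
  if (length(b$power) == 1L) return(0)
  p <- b$power / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(b$power))
}

#' Relative gastric band powers
#'
#' Power in each of the bradygastric, normogastric and tachygastric bands
#' divided by total passband power.
#'
#' @inheritParams spectral_entropy
#' @param bands_cpm list of three (lo, hi) cpm intervals, defaults
#'   3-8, 8-11, 11-15 cpm.
#' @return named list `bp1`, `bp2`, `bp3`.
#' @export
band_powers <- function(psd,
                        bands_cpm = list(c(3, 8), c(8, 11), c(11, 15)),
                        band_cpm = c(0.6, 30)) {
  total <- sum(.psd_band(psd, band_cpm)$power)
  if (!(total > 0)) stop("zero total power in band", call. = FALSE)
  # right-open intervals: adjacent bands share an edge, each bin counts once
  bp <- vapply(bands_cpm, function(b) {
    keep <- psd$freqs_cpm >= b[1] & psd$freqs_cpm < b[2]
    sum(psd$power[keep]) / total
  }, numeric(1))
  list(bp1 = bp[1], bp2 = bp[2], bp3 = bp[3])
}

#' Crest factor of the PSD
#'
#' `max(power) / rms(power)` over the passband; 1 for a flat spectrum,
#' `sqrt(k)` for a single spike among `k` bins.
#'
#' @inheritParams spectral_entropy
#' @return scalar >= 1.
#' @export
psd_crest_factor <- function(psd, band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, band_cpm)
  r <- sqrt(mean(b$power^2))
  if (!(r > 0)) stop("zero power in band", call. = FALSE)
  max(b$power) / r
}

#' Median frequency
#'
#' Smallest grid frequency at which cumulative passband power reaches 50%
#' of the total.
#'
#' @inheritParams spectral_entropy
#' @return frequency in cpm.
#' @export
median_frequency <- function(psd, band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, band_cpm)
  tot <- sum(b$power)
  if (!(tot > 0)) stop("zero total power in band", call. = FALSE)
  b$freqs[which(cumsum(b$power) >= tot / 2)[1]]
}

#' Mean power frequency
#'
#' Power-weighted mean frequency over the passband.
#'
#' @inheritParams spectral_entropy
#' @return frequency in cpm.
#' @export
mean_power_frequency <- function(psd, band_cpm = c(0.6, 30)) {
  b <- .psd_band(psd, band_cpm)
  tot <- sum(b$power)
  if (!(tot > 0)) stop("zero total power in band", call. = FALSE)
  sum(b$freqs * b$power) / tot
}
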