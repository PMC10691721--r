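#' @title Window feature extraction
#' @description Assembles the 27-feature battery (17 time-domain, 10
#'   frequency-domain) for each pre-processed window into a feature table
#'   ready for selection and classification.
#' @name features
NULL

#' Feature-extraction configuration
#'
#' @param apen_m,apen_r_factor approximate-entropy template length and
#'   tolerance factor (x SD).
#' @param sampen_m,sampen_r_factor sample-entropy template length and
#'   tolerance factor.
#' @param perm_order,perm_delay permutation-entropy embedding.
#' @param svd_order,svd_delay SVD-entropy embedding.
#' @param psd_resolution_cpm Welch grid spacing, cpm.
#' @param df_band_cpm dominant-frequency search band / passband, cpm.
#' @param bands_cpm the three gastric bands (bradygastria, normogastria,
#'   tachygastria), cpm.
#' @return object of class `egg_feature_config`.
#' @export
feature_config <- function(apen_m = 2L, apen_r_factor = 0.2,
                           sampen_m = 2L, sampen_r_factor = 0.2,
                           perm_order = 3L, perm_delay = 1L,
                           svd_order = 3L, svd_delay = 1L,
                           psd_resolution_cpm = 0.1,
                           df_band_cpm = c(0.6, 30),
                           bands_cpm = list(c(3, 8), c(8, 11), c(11, 15))) {
  stopifnot(psd_resolution_cpm > 0, df_band_cpm[1] < df_band_cpm[2])
  structure(as.list(environment()), class = "egg_feature_config")
}

#' Names of the 27 window features, in fixed column order
#' @return character vector.
#' @export
feature_names <- function() {
  c("mean", "variance", "mode", "median", "skewness", "kurtosis",
    "rms", "ll", "apen", "smen", "pren", "svden", "lz",
    "hjorth_mobility", "hjorth_complexity", "pfd", "hurst",
    "df", "dp", "pmmp", "spen", "bp1", "bp2", "bp3",
    "crest_factor", "mf", "mpf")
}

#' Extract the full feature vector from one window
#'
#' Computes all 27 features and carries forward the window's `removed_pct`,
#' label and metadata.
#'
#' @param window an `egg_window` from [preprocess_recording()], or any list
#'   with `samples` and `fs_hz`.
#' @param config a [feature_config()].
#' @return one-row `data.frame`: the 27 features in [feature_names()] order,
#'   then `removed_pct`, `label`, `stim_freq_hz`, `subject_id`,
#'   `session_id`, `start_time_s`.
#' @export
extract_features <- function(window, config = feature_config()) {
  x <- window$samples
  fs <- window$fs_hz
  # zero-variance windows carry no spectral information: the PSD-based
  # descriptors and the Hurst slope are undefined and fall back to 0
  degenerate <- stats::var(x) == 0
  if (degenerate)
    warning("zero-variance window; spectral features set to 0")
  mom <- statistical_moments(x)
  hj <- hjorth_params(x)
  if (degenerate) {
    dfp <- list(df = 0, dp = 0)
    bp <- list(bp1 = 0, bp2 = 0, bp3 = 0)
  } else {
    psd <- welch_psd(x, fs, config$psd_resolution_cpm)
    dfp <- dominant_freq_power(psd, config$df_band_cpm)
    bp <- band_powers(psd, config$bands_cpm, config$df_band_cpm)
  }
  out <- data.frame(
    mean = mom$mean, variance = mom$variance, mode = mom$mode,
    median = mom$median, skewness = mom$skewness, kurtosis = mom$kurtosis,
    rms = rms(x), ll = line_length(x),
    apen = approx_entropy(x, config$apen_m, config$apen_r_factor),
    smen = sample_entropy(x, config$sampen_m, config$sampen_r_factor),
    pren = permutation_entropy(x, config$perm_order, config$perm_delay),
    svden = svd_entropy(x, config$svd_order, config$svd_delay),
    lz = lempel_ziv(x),
    hjorth_mobility = hj$mobility, hjorth_complexity = hj$complexity,
    pfd = petrosian_fd(x),
    hurst = if (degenerate) 0.5 else hurst_exponent(x),
    df = dfp$df, dp = dfp$dp,
    pmmp = if (degenerate) 0 else pmmp(psd, config$df_band_cpm),
    spen = if (degenerate) 0 else spectral_entropy(psd, config$df_band_cpm),
    bp1 = bp$bp1, bp2 = bp$bp2, bp3 = bp$bp3,
    crest_factor = if (degenerate) 0 else
      psd_crest_factor(psd, config$df_band_cpm),
    mf = if (degenerate) 0 else median_frequency(psd, config$df_band_cpm),
    mpf = if (degenerate) 0 else
      mean_power_frequency(psd, config$df_band_cpm),
    stringsAsFactors = FALSE)
  out$removed_pct <- if (!is.null(window$removed_pct)) window$removed_pct else NA_real_
  out$label <- if (!is.null(window$label)) window$label else NA_character_
  out$stim_freq_hz <- if (!is.null(window$stim_freq_hz)) window$stim_freq_hz else NA_real_
  out$subject_id <- if (!is.null(window$subject_id)) window$subject_id else NA_character_
  out$session_id <- if (!is.null(window$session_id)) window$session_id else NA_character_
  out$start_time_s <- if (!is.null(window$start_time_s)) window$start_time_s else NA_real_
  out
}

#' Build a feature table from a list of windows
#'
#' @param windows list of `egg_window` objects.
#' @param config a [feature_config()].
#' @return `data.frame` with one row per window.
#' @export
feature_table <- function(windows, config = feature_config()) {
  if (length(windows) == 0)
    stop("no windows to extract features from", call. = FALSE)
  do.call(rbind, lapply(windows, extract_features, config = config))
}

#' Write / read a feature table as tab-delimited text
#'
#' Full float precision; header row in [feature_names()] order followed by
#' the bookkeeping columns.
#'
#' @param table a feature table.
#' @param path file path.
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(format(table, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
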