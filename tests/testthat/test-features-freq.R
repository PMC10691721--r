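# a 60 s window at 4 Hz, like the pipeline produces
sine_window <- function(f_cpm, fs = 4, dur = 60, amp = 1) {
  t <- (0:(dur * fs - 1)) / fs
  amp * sin(2 * pi * (f_cpm / 60) * t)
}

# hand-built PSD objects for the descriptor closed forms
psd_stub <- function(power, freqs = seq_along(power)) {
  structure(list(freqs_cpm = freqs, power = power,
                 resolution_cpm = diff(freqs[1:2])),
            class = "egg_psd")
}

test_that("the Welch grid, Parseval sum and peak location are right", {
  x <- sine_window(10)
  psd <- welch_psd(x, 4, resolution_cpm = 0.1)
  expect_equal(unique(round(diff(psd$freqs_cpm), 10)), 0.1)
  expect_equal(psd$resolution_cpm, 0.1)
  # Parseval with Hann correction: sum power * df ~ variance
  withr::with_seed(2, z <- rnorm(240))
  pz <- welch_psd(z, 4, 0.1)
  expect_equal(sum(pz$power) * 0.1, var(z) * 239 / 240, tolerance = 0.05)
  # argmax at the sine frequency
  expect_equal(psd$freqs_cpm[which.max(psd$power)], 10)
  expect_warning(welch_psd(z, 4, resolution_cpm = 5), "coarser")
})

test_that("dominant frequency, power and the tie rule", {
  psd <- welch_psd(sine_window(10), 4, 0.1)
  dfp <- dominant_freq_power(psd)
  expect_equal(dfp$df, 10)
  expect_equal(dfp$dp, max(psd$power[psd$freqs_cpm >= 0.6 &
                                       psd$freqs_cpm <= 30]))
  # two equal peaks: lowest frequency wins
  ps <- psd_stub(c(0, 5, 0, 5, 0), freqs = c(2, 6, 9, 12, 20))
  expect_equal(dominant_freq_power(ps, c(0.6, 30))$df, 6)
  expect_error(dominant_freq_power(ps, c(40, 50)), "band")
})

test_that("PMMP counts strict exceedances of DP/4", {
  expect_equal(pmmp(psd_stub(rep(3, 8), freqs = 1:8), c(0.6, 30)), 100)
  expect_equal(pmmp(psd_stub(c(8, 2, 1, 1), freqs = c(2, 5, 8, 11)),
                    c(0.6, 30)), 25)   # DP/4 = 2, strictly greater: 1 bin
  p50 <- c(10, rep(0, 49))
  expect_equal(pmmp(psd_stub(p50, freqs = 1:50), c(0.6, 30)),
               100 * 1 / 30)           # bins 1..30 cpm inside the band
})

test_that("spectral entropy of simple spectra", {
  expect_equal(spectral_entropy(psd_stub(c(0, 7, 0), 1:3), c(0.6, 30)), 0)
  expect_equal(spectral_entropy(psd_stub(rep(2, 10), 1:10), c(0.6, 30)), 1)
  expect_equal(spectral_entropy(psd_stub(c(0.5, 0.5), 1:2), c(0.6, 30)), 1)
  expect_equal(spectral_entropy(psd_stub(c(0.9, 0.1), 1:2), c(0.6, 30)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2),
               tolerance = 1e-12)
  expect_equal(spectral_entropy(psd_stub(c(0.9, 0.1), 1:2), c(0.6, 30)),
               0.4690, tolerance = 1e-3)
  expect_error(spectral_entropy(psd_stub(c(0, 0), 1:2), c(0.6, 30)), "power")
})

test_that("band powers split the passband as expected", {
  # resolved 10 cpm line (10-minute signal): normogastric band dominates
  psd <- welch_psd(sine_window(10, dur = 600), 4, 0.1)
  bp <- band_powers(psd)
  expect_gte(bp$bp2, 0.95)
  expect_lte(bp$bp1 + bp$bp3, 0.05)
  expect_lte(bp$bp1 + bp$bp2 + bp$bp3, 1 + 1e-12)
  # one 60 s window: the wider main lobe still leaves bp2 dominant
  bp60 <- band_powers(welch_psd(sine_window(10), 4, 0.1))
  expect_gt(bp60$bp2, 0.9)
  expect_lte(bp60$bp1 + bp60$bp2 + bp60$bp3, 1 + 1e-12)
  # all power at 20 cpm: outside every gastric band
  ps <- psd_stub(c(rep(0, 19), 5, rep(0, 5)), freqs = 1:25)
  bp20 <- band_powers(ps)
  expect_equal(unlist(bp20), c(bp1 = 0, bp2 = 0, bp3 = 0))
  # flat spectrum: proportional to the 5:3:4 cpm bandwidths
  flat <- psd_stub(rep(1, 30), freqs = 1:30)
  bpf <- band_powers(flat)
  expect_equal(unlist(bpf) * 30, c(bp1 = 5, bp2 = 3, bp3 = 4))
})

test_that("crest factor, median and mean power frequency closed forms", {
  expect_equal(psd_crest_factor(psd_stub(rep(4, 12), 1:12), c(0.6, 30)), 1)
  expect_equal(psd_crest_factor(psd_stub(c(3, 4), 1:2), c(0.6, 30)),
               4 / sqrt((9 + 16) / 2), tolerance = 1e-12)
  k <- 25
  spike <- psd_stub(c(9, rep(0, k - 1)), freqs = 1:25)
  expect_equal(psd_crest_factor(spike, c(0.6, 30)), sqrt(k))

  two <- psd_stub(c(1, 1), freqs = c(5, 15))
  expect_equal(mean_power_frequency(two, c(0.6, 30)), 10)
  expect_equal(median_frequency(two, c(0.6, 30)), 5)  # first 50% crossing
  one <- psd_stub(6, freqs = 10)
  expect_equal(median_frequency(one, c(0.6, 30)), 10)
  expect_equal(mean_power_frequency(one, c(0.6, 30)), 10)
  withr::with_seed(11, pw <- runif(40))
  ps <- psd_stub(pw, freqs = seq(0.5, 20, by = 0.5))
  expect_equal(mean_power_frequency(ps, c(0.6, 30)),
               sum(ps$freqs_cpm[-1] * pw[-1]) / sum(pw[-1]),
               tolerance = 1e-10)   # bin at 0.5 cpm is outside the band
})

test_that("a full feature vector has the expected structure and values", {
  win <- list(samples = sine_window(10, amp = 100) +
                sine_window(4.4, amp = 3),   # faint second line
              fs_hz = 4, removed_pct = 1.5, label = "baseline",
              stim_freq_hz = 0, subject_id = "s1", session_id = "a",
              start_time_s = 0)
  fv <- extract_features(win)
  expect_equal(fv$df, 10)
  expect_gt(fv$bp2, 0.9)
  expect_lt(fv$pfd, 1.01)
  expect_equal(fv$removed_pct, 1.5)
  expect_identical(names(fv)[1:27], feature_names())
  expect_false(anyNA(fv[, feature_names()]))
})

test_that("features respect amplitude-scale and time-reversal invariances", {
  withr::with_seed(33, {
    x <- sine_window(9, amp = 150) + rnorm(240, sd = 30)
  })
  mkwin <- function(v) list(samples = v, fs_hz = 4, removed_pct = 0,
                            label = "baseline", stim_freq_hz = 0,
                            subject_id = "s", session_id = "s",
                            start_time_s = 0)
  f1 <- extract_features(mkwin(x))
  f2 <- extract_features(mkwin(2 * x))
  scale_invariant <- c("smen", "apen", "pren", "svden", "pfd", "spen",
                       "bp1", "bp2", "bp3", "mf", "mpf", "crest_factor",
                       "hjorth_mobility", "hjorth_complexity", "df")
  for (f in scale_invariant) {
    expect_equal(f2[[f]], f1[[f]], tolerance = 1e-8, label = f)
  }
  expect_equal(f2$rms, 2 * f1$rms)
  expect_equal(f2$ll, 2 * f1$ll)
  expect_equal(f2$variance, 4 * f1$variance)

  f3 <- extract_features(mkwin(rev(x)))
  for (f in c("mean", "variance", "median", "rms", "ll", "pfd", "spen",
              "df", "dp", "bp1", "bp2", "bp3", "mf", "mpf",
              "crest_factor", "pmmp", "skewness", "kurtosis")) {
    expect_equal(f3[[f]], f1[[f]], tolerance = 1e-9, label = f)
  }
})

test_that("a constant window exercises every degenerate fallback", {
  win <- list(samples = rep(5, 240), fs_hz = 4, removed_pct = 0,
              label = "baseline", stim_freq_hz = 0, subject_id = "s",
              session_id = "s", start_time_s = 0)
  expect_error(suppressWarnings(extract_features(win)), NA)
})
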