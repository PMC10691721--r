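test_that("spike excision deletes exactly the out-of-range samples", {
  r <- excise_extreme(c(0, 5, 2e8, -3), 1e8)
  expect_equal(r$samples, c(0, 5, -3))
  expect_equal(r$excised_count, 1L)

  r2 <- excise_extreme(c(1, -2, 3), 1e8)
  expect_equal(r2$samples, c(1, -2, 3))
  expect_equal(r2$excised_count, 0L)

  r3 <- excise_extreme(numeric(0), 1e8)
  expect_equal(r3$excised_count, 0L)
  expect_length(r3$samples, 0)

  # seeded synthetic: count agrees with a linear scan of the raw array
  p <- generator_params(seed = 13, spike_rate_per_min = 2)
  rec <- generate_recording("baseline", p, duration_s = 600, fs_hz = 100)
  r4 <- excise_extreme(rec$samples, 1e8)
  expect_equal(r4$excised_count, sum(abs(rec$samples) > 1e8))
  expect_gt(r4$excised_count, 0)
})

test_that("the DCT equals a naive O(N^2) oracle and round-trips", {
  withr::with_seed(8, {
    for (n in c(2, 7, 33, 64, 101)) {
      x <- rnorm(n)
      expect_equal(dct_ii(x), oracle_dct_ii(x), tolerance = 1e-10)
      expect_equal(dct_iii(dct_ii(x)), x, tolerance = 1e-10)
    }
    # prime lengths exercise the chirp-z path
    x <- rnorm(1009)
    expect_equal(dct_ii(x), oracle_dct_ii(x), tolerance = 1e-8)
  })
})

test_that("the index-blocked band-pass has the stated filter properties", {
  withr::with_seed(4, x <- rnorm(2000))
  fs <- 10
  # all-pass round trip
  expect_equal(ibdctfm_bandpass(x, fs, 0, fs / 2), x, tolerance = 1e-9)
  # DC rejection
  const <- rep(50, 1200)
  filt <- ibdctfm_bandpass(const, fs, 0.01, 0.5)
  expect_lt(abs(mean(filt)), 1e-6 * 50)
  # two-tone: 0.1 Hz preserved, 5 Hz attenuated >= 40 dB (FFT oracle)
  t <- (0:119999) / 200
  two <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 5 * t)
  f2 <- ibdctfm_bandpass(two, 200, 0.01, 0.5)
  in_before <- oracle_band_power(two, 200, 0.09, 0.11)
  in_after <- oracle_band_power(f2, 200, 0.09, 0.11)
  out_before <- oracle_band_power(two, 200, 4.9, 5.1)
  out_after <- oracle_band_power(f2, 200, 4.9, 5.1)
  expect_equal(in_after / in_before, 1, tolerance = 0.01)
  expect_lt(out_after / out_before, 1e-4)    # >= 40 dB
  # idempotence
  once <- ibdctfm_bandpass(x, fs, 0.2, 2)
  twice <- ibdctfm_bandpass(once, fs, 0.2, 2)
  expect_equal(twice, once, tolerance = 1e-9)
  expect_error(ibdctfm_bandpass(x, fs, 3, 1), "band")
})

test_that("clamping substitutes the pre-substitution mean", {
  r <- clamp_substitute(c(0, 3000, -100), 2000)
  expect_equal(r$samples, c(0, mean(c(0, 3000, -100)), -100))
  expect_equal(r$substituted_count, 1L)

  r2 <- clamp_substitute(c(10, -20, 30), 2000)
  expect_equal(r2$samples, c(10, -20, 30))
  expect_equal(r2$substituted_count, 0L)

  # corner case forced by the rule: the mean itself is out of range
  r3 <- clamp_substitute(c(5000, 5000), 2000)
  expect_equal(r3$samples, c(5000, 5000))
  expect_equal(r3$substituted_count, 2L)
})

test_that("removed-pct arithmetic and the 30% boundary", {
  expect_equal(compute_removed_pct(0, 0, 1000), 0)
  expect_equal(compute_removed_pct(10, 20, 1000), 3)
  expect_equal(compute_removed_pct(300, 0, 1000), 30)
  expect_error(compute_removed_pct(1, 0, 0), "raw_length")
})

test_that("decimation picks every k-th sample and preserves in-band RMS", {
  x <- seq_len(120000)
  d <- decimate_signal(x, 2000, 4)
  expect_length(d$samples, 240)
  expect_equal(d$fs_hz, 4)
  expect_equal(d$samples[1:3], c(1, 501, 1001))
  expect_identical(decimate_signal(x, 2000, 2000)$samples, x)
  expect_error(decimate_signal(x, 2000, 3), "integer")
  t <- (0:(2000 * 100 - 1)) / 2000
  s <- sin(2 * pi * 0.1 * t)
  ds <- decimate_signal(s, 2000, 4)
  expect_equal(rms(ds$samples), 1 / sqrt(2), tolerance = 0.005)
})

test_that("windowing counts follow floor((T - window) / step) + 1", {
  mk <- function(T_s) segment_windows(rep(0, T_s * 4), 4, 60, 20)
  w600 <- mk(600)
  expect_length(w600, 14)
  expect_equal(vapply(w600, `[[`, 0, "start_time_s"), seq(0, 520, by = 40))
  expect_length(mk(60), 1)
  expect_length(mk(99), 1)
  expect_warning(w10 <- segment_windows(rep(0, 40), 4, 60, 20), "shorter")
  expect_length(w10, 0)
})

test_that("the full chain drops exactly the windows a brute-force recount drops", {
  # clean recording: 14 windows, removed_pct all zero
  rec <- generate_recording("baseline", clean_params(seed = 31),
                            duration_s = 600, fs_hz = 100)
  w <- preprocess_recording(rec, preprocess_config())
  expect_length(w, 14)
  expect_true(all(vapply(w, `[[`, 0, "removed_pct") == 0))

  # plant a dense artifact region overlapping windows 3-4 only
  fs <- 100
  x <- rec$samples
  x[(100 * fs):(160 * fs)] <- x[(100 * fs):(160 * fs)] + 5e8
  rec2 <- egg_recording(x, fs, condition = "baseline")
  cfg <- preprocess_config()
  w2 <- preprocess_recording(rec2, cfg)

  # independent recount: windows segment the post-excision signal, but each
  # excised sample is attributed to the window spanning its original time
  bad_t <- (which(abs(x) > 1e8) - 1) / fs
  n_kept <- sum(abs(x) <= 1e8)
  n_dec <- floor((n_kept - 1) / (fs / 4)) + 1      # samples after decimation
  n_win <- floor((n_dec - 60 * 4) / (40 * 4)) + 1
  starts <- (seq_len(n_win) - 1) * 40
  frac <- vapply(starts, function(s0)
    sum(bad_t >= s0 & bad_t < s0 + 60) / (60 * fs), numeric(1))
  expect_equal(vapply(w2, `[[`, 0, "start_time_s"), starts[frac < 0.3])
  expect_equal(attr(w2, "n_windows_dropped"), sum(frac >= 0.3))
  expect_gt(sum(frac >= 0.3), 0)
})

test_that("the band-pass removes the VNS pulse-train artifact", {
  p <- clean_params(seed = 41, vns_pulse_freq_hz = 10,
                    vns_pulse_amp_uv = 5000)
  rec <- generate_recording("vns", p, duration_s = 300, fs_hz = 200)
  filt <- ibdctfm_bandpass(rec$samples, 200, 0.01, 0.5)
  before <- oracle_band_power(rec$samples, 200, 1, 100)
  after <- oracle_band_power(filt, 200, 1, 100)
  expect_lt(after / before, 1e-4)   # >= 40 dB on the >= 1 Hz residual
})

test_that("removed-pct is invariant to rescaling the in-range signal", {
  withr::with_seed(6, base <- 500 * sin(2 * pi * (1:60000) * 0.003) +
                     rnorm(60000, sd = 50))
  spikes <- sample(60000, 20)
  x <- base
  x[spikes] <- 5e8
  cfg <- preprocess_config(window_s = 60, overlap_s = 20,
                           decimate_to_hz = 4)
  rp <- function(sig) {
    w <- preprocess_recording(egg_recording(sig, 100), cfg)
    vapply(w, `[[`, 0, "removed_pct")
  }
  x_scaled <- base * 2
  x_scaled[spikes] <- 5e8
  expect_equal(rp(x), rp(x_scaled))
})
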