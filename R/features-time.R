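#' @title Time-domain window features
#' @description Amplitude statistics, regularity/complexity entropies,
#'   Hjorth parameters, Petrosian fractal dimension and the rescaled-range
#'   Hurst exponent, computed per pre-processed window.
#' @name time_features
NULL

#' Distribution statistics of a window
#'
#' Population (1/N) moments: mean, variance, mode, median, standardized
#' skewness and excess (Fisher) kurtosis. The mode of a continuous signal is
#' defined as the midpoint of the most populated of 64 equal-width histogram
#' bins (lowest bin wins ties).
#'
#' @param x numeric vector, length >= 2.
#' @param n_bins number of histogram bins for the mode.
#' @return named list: mean, variance, mode, median, skewness, kurtosis.
#' @export
statistical_moments <- function(x, n_bins = 64L) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    warning("zero variance; skewness and kurtosis set to 0")
    return(list(mean = mu, variance = 0, mode = x[1], median = mu,
                skewness = 0, kurtosis = 0))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  rng <- range(x)
  if (diff(rng) == 0) {
    mode_val <- x[1]
  } else {
    width <- diff(rng) / n_bins
    bin <- pmin(floor((x - rng[1]) / width), n_bins - 1L)
    counts <- tabulate(bin + 1L, nbins = n_bins)
    best <- which.max(counts)           # ties -> lowest bin
    mode_val <- rng[1] + (best - 0.5) * width
  }
  list(mean = mu, variance = m2, mode = mode_val,
       median = stats::median(x),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Root mean square
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  stopifnot(length(x) >= 1)
  sqrt(mean(x^2))
}

#' Line length
#'
#' Sum of absolute successive differences, an approximation of Katz's
#' fractal dimension used widely in EEG analysis.
#'
#' @param x numeric vector, length >= 2.
#' @return `sum(abs(diff(x)))`.
#' @export
line_length <- function(x) {
  stopifnot(length(x) >= 2)
  sum(abs(diff(x)))
}

# Chebyshev-distance template match counts for length-m templates.
# Returns, for each template start i, the number of j with
# max_k |x[i+k] - x[j+k]| <= r (self-match included).
.template_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m + 1L
  d <- abs(outer(x[1:nt], x[1:nt], "-"))
  ok <- d <= r
  if (m > 1L) {
    for (k in 1:(m - 1L)) {
      dk <- abs(outer(x[(1 + k):(nt + k)], x[(1 + k):(nt + k)], "-"))
      ok <- ok & (dk <= r)
    }
  }
  rowSums(ok)
}

#' Approximate entropy (Pincus)
#'
#' `ApEn = phi(m) - phi(m + 1)` with `phi(m)` the mean log fraction of
#' templates within Chebyshev distance `r` (self-matches included),
#' `r = r_factor * sd(x)`.
#'
#' @param x numeric vector, length >= m + 2.
#' @param m template length (default 2).
#' @param r_factor tolerance as a multiple of the sample SD (default 0.2).
#' @return nonnegative scalar; 0 (with a warning) for a constant signal.
#' @export
approx_entropy <- function(x, m = 2L, r_factor = 0.2) {
  n <- length(x)
  stopifnot(n >= m + 2)
  r <- r_factor * stats::sd(x)
  if (!(r > 0)) {
    warning("zero SD; approximate entropy set to 0")
    return(0)
  }
  phi <- function(mm) {
    nt <- n - mm + 1L
    mean(log(.template_counts(x, mm, r) / nt))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (Richman & Moorman)
#'
#' `SampEn = -log(A / B)` where `B` (`A`) counts length-`m` (`m + 1`)
#' template pairs within Chebyshev distance `r`, self-matches excluded;
#' `r = r_factor * sd(x)`. Both counts use the `n - m` templates that admit
#' an `m + 1` extension.
#'
#' @inheritParams approx_entropy
#' @return nonnegative scalar; `Inf` when no length-`m + 1` pair matches;
#'   0 (with a warning) for a constant signal.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.2) {
  n <- length(x)
  stopifnot(n >= m + 2)
  r <- r_factor * stats::sd(x)
  if (!(r > 0)) {
    warning("zero SD; sample entropy set to 0")
    return(0)
  }
  count_pairs <- function(mm) {
    nt <- n - m                      # same template count at both lengths
    cnt <- .template_counts(x[1:(nt + mm - 1L)], mm, r)
    (sum(cnt) - nt) / 2              # drop self-matches, unordered pairs
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0 || A == 0) {
    warning("no matching templates; sample entropy is Inf")
    return(Inf)
  }
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of delay-embedded
#' subsequences, normalized by `log(order!)` to \[0, 1\]. Ties are broken by
#' index order (stable sort).
#'
#' @param x numeric vector.
#' @param order embedding dimension (default 3).
#' @param delay embedding delay (default 1).
#' @return value in \[0, 1\]; 0 when a single pattern dominates.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  stopifnot(n >= (order - 1L) * delay + 2L, order >= 2L, delay >= 1L)
  n_pat <- n - (order - 1L) * delay
  emb <- sapply(0:(order - 1L), function(k) x[(1:n_pat) + k * delay])
  codes <- apply(emb, 1L, function(v) {
    paste(order(v), collapse = "")     # order() is stable: ties by index
  })
  p <- table(codes) / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

#' Singular value decomposition entropy
#'
#' Shannon entropy of the normalized singular values of the delay-embedding
#' trajectory matrix, normalized by `log(order)`.
#'
#' @inheritParams permutation_entropy
#' @return value in \[0, 1\]; 0 for a rank-deficient (e.g. constant) signal.
#' @export
svd_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  stopifnot(n >= order, order >= 2L, delay >= 1L)
  n_row <- n - (order - 1L) * delay
  stopifnot(n_row >= 1L)
  mat <- sapply(0:(order - 1L), function(k) x[(1:n_row) + k * delay])
  sv <- svd(matrix(mat, nrow = n_row))$d
  tot <- sum(sv)
  if (tot == 0) return(0)
  p <- sv / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(order)
}

#' Lempel-Ziv complexity (LZ76)
#'
#' Binarizes the signal at its median (`x >= median -> 1`) and counts the
#' phrases of the LZ76 exhaustive parsing.
#'
#' @param x numeric vector, length >= 2.
#' @param normalize if `TRUE`, multiply by `log2(n) / n` (asymptotic
#'   normalization); default `FALSE` returns the raw phrase count.
#' @return phrase count (or its normalized value).
#' @export
lempel_ziv <- function(x, normalize = FALSE) {
  stopifnot(length(x) >= 2)
  s <- as.integer(x >= stats::median(x))
  n <- length(s)
  # Kaspar-Schuster exhaustive parsing
  i <- 0L; c <- 1L; l <- 1L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] != s[l + k]) {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c <- c + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    } else {
      k <- k + 1L
      if (l + k > n) {
        c <- c + 1L
        break
      }
    }
  }
  if (normalize) c * log2(n) / n else as.numeric(c)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal, converging to
#' 1 for a pure sine.
#'
#' @param x numeric vector, length >= 3.
#' @return named list with `mobility` and `complexity`; `(0, 0)` with a
#'   warning for a zero-variance signal.
#' @export
hjorth_params <- function(x) {
  stopifnot(length(x) >= 3)
  v0 <- stats::var(x)
  if (!(v0 > 0)) {
    warning("zero variance; Hjorth parameters set to 0")
    return(list(mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  mob1 <- if (v1 > 0) sqrt(v2 / v1) else 0
  list(mobility = mob, complexity = if (mob > 0) mob1 / mob else 0)
}

#' Petrosian fractal dimension
#'
#' `PFD = log10(N) / (log10(N) + log10(N / (N + 0.4 * Ndelta)))` where `N` is
#' the window length and `Ndelta` the number of sign changes in the first
#' difference (zero differences carry the previous sign).
#'
#' @param x numeric vector, length >= 3.
#' @return value >= 1; exactly 1 for a monotone signal.
#' @export
petrosian_fd <- function(x) {
  stopifnot(length(x) >= 3)
  n <- length(x)
  s <- sign(diff(x))
  # zeros inherit the previous non-zero sign
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  }
  n_delta <- sum(diff(s) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))
}

#' Hurst exponent by rescaled-range analysis
#'
#' Slope of `log(R/S)` against `log(window size)` over dyadic window sizes,
#' where for each block `R` is the range of the cumulative deviations from
#' the block mean and `S` the block standard deviation.
#'
#' @param x numeric vector, length >= 100.
#' @param min_block smallest block size (default 8).
#' @return estimated Hurst exponent (~0.5 for white noise, ~1 for a random
#'   walk).
#' @export
hurst_exponent <- function(x, min_block = 8L) {
  n <- length(x)
  if (n < 100) stop("need at least 100 samples", call. = FALSE)
  sizes <- c()
  m <- min_block
  while (m <= n %/% 2) {
    sizes <- c(sizes, m)
    m <- m * 2L
  }
  rs <- vapply(sizes, function(sz) {
    n_blk <- n %/% sz
    vals <- vapply(seq_len(n_blk), function(b) {
      seg <- x[((b - 1L) * sz + 1L):(b * sz)]
      s <- stats::sd(seg)
      if (!(s > 0)) return(NA_real_)
      dev <- cumsum(seg - mean(seg))
      (max(dev) - min(dev)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) stop("degenerate signal: R/S undefined", call. = FALSE)
  stats::coef(stats::lm(log(rs[keep]) ~ log(sizes[keep])))[[2]]
}
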