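# Brute-force / closed-form oracles, kept deliberately naive and independent
# of the package implementations they check.

# direct O(N^2) orthonormal DCT-II
oracle_dct_ii <- function(x) {
  n <- length(x)
  ks <- 0:(n - 1)
  coef <- vapply(ks, function(k) {
    sum(x * cos(pi * (2 * (0:(n - 1)) + 1) * k / (2 * n)))
  }, numeric(1))
  coef * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

# FFT band power of a signal in [lo_hz, hi_hz]
oracle_band_power <- function(x, fs, lo_hz, hi_hz) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sum(sp[f >= lo_hz & f <= hi_hz])
}

# naive double-loop approximate entropy (Pincus, self-matches included)
oracle_apen <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logc <- numeric(nt)
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      }
      logc[i] <- log(cnt / nt)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

# naive double-loop sample entropy (self-matches excluded; both template
# lengths use the first n - m templates)
oracle_sampen <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  count <- function(mm) {
    nt <- n - m
    cnt <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# exhaustive ordinal-pattern permutation entropy (ties by index order)
oracle_pren <- function(x, order = 3, delay = 1) {
  n_pat <- length(x) - (order - 1) * delay
  pats <- character(n_pat)
  for (i in 1:n_pat) {
    v <- x[i + (0:(order - 1)) * delay]
    pats[i] <- paste(rank(v, ties.method = "first"), collapse = "")
  }
  p <- table(pats) / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

# SVD entropy through the eigenvalues of the Gram matrix
oracle_svden <- function(x, order = 3, delay = 1) {
  n_row <- length(x) - (order - 1) * delay
  mat <- sapply(0:(order - 1), function(k) x[(1:n_row) + k * delay])
  ev <- eigen(crossprod(matrix(mat, nrow = n_row)),
              symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))
  p <- sv / sum(sv)
  p <- p[p > 0]
  -sum(p * log(p)) / log(order)
}

# LZ76 exhaustive parsing by explicit substring search
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    while (i + k - 1L <= n &&
           grepl(substr(s, i, i + k - 1L), substr(s, 1, i + k - 2L),
                 fixed = TRUE)) {
      k <- k + 1L
    }
    c <- c + 1L
    i <- i + k
  }
  c
}

# O(n^2) pairwise AUC with half credit for ties
oracle_auc <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive two-sample ECDF sup-distance
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# iid-noise feature table with n_signal planted class-separating columns
make_planted_table <- function(n = 60, p = 10, n_signal = 3, effect = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("baseline", "vns"), length.out = n))
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    colnames(X) <- sprintf("f%02d", seq_len(p))
    for (j in seq_len(n_signal)) {
      X[[j]] <- X[[j]] + effect * (as.integer(y) - 1) *
        (if (j %% 2 == 0) -1 else 1)
    }
    list(X = X, y = y,
         planted = colnames(X)[seq_len(n_signal)])
  })
}

# quiet generator: clean slow wave only
clean_params <- function(...) {
  generator_params(freq_jitter_sd_cpm = 0, pink_noise_sd_uv = 0,
                   spike_rate_per_min = 0, motion_artifact_rate_per_min = 0,
                   harmonic_weight = 0, ...)
}
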