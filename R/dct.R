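#' @title Discrete cosine transform utilities
#' @description Orthonormal DCT-II/DCT-III pair used by the index-blocked
#'   band-pass filter, computed through length-N FFTs of an even/odd
#'   re-ordering of the input (Makhoul's identity), so the filter stays
#'   zero-phase and the forward/inverse round trip is numerically tight.
#' @name dct
NULL

# largest prime factor; stats::fft degrades to O(n*p) when a large prime p
# divides n, so lengths with big factors are routed through Bluestein below
.max_prime_factor <- function(n) {
  if (n <= 1L) return(1L)
  mx <- 1L
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) {
      mx <- max(mx, d)
      n <- n %/% d
    }
    d <- d + 1L
  }
  max(mx, n)
}

# smallest 5-smooth integer >= n (fast FFT length)
.next_smooth <- function(n) {
  if (n <= 1) return(1)
  best <- Inf
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      # smallest power of 2 lifting p35 to >= n
      rem <- max(1, ceiling(n / p35))
      cand <- p35 * 2^ceiling(log2(rem))
      if (cand >= n) best <- min(best, cand)
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  best
}

# arbitrary-length FFT via Bluestein's chirp-z algorithm (5-smooth FFTs)
.bluestein_fft <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 1 else -1
  k <- 0:(n - 1)
  # exp(sgn * i*pi*k^2/n); k^2 taken mod 2n to avoid precision loss at large k
  ksq <- (as.numeric(k) * k) %% (2 * n)
  chirp <- exp(sgn * 1i * pi * ksq / n)
  m <- .next_smooth(2 * n - 1)
  a <- c(x * chirp, rep(0i, m - n))
  b <- rep(0i, m)
  b[1] <- Conj(chirp[1])
  b[2:n] <- Conj(chirp[2:n])
  b[m - (1:(n - 1)) + 1] <- Conj(chirp[2:n])
  conv <- stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE) / m
  chirp * conv[1:n]
}

# FFT that stays O(n log n) for any length
.fft_any <- function(x, inverse = FALSE) {
  n <- length(x)
  if (n < 2L || .max_prime_factor(n) <= 127L) {
    stats::fft(x, inverse = inverse)
  } else {
    .bluestein_fft(x, inverse = inverse)
  }
}

#' Orthonormal type-II discrete cosine transform
#'
#' Computes `X[k] = s_k * sum_n x[n] cos(pi*(2n+1)*k/(2N))` with
#' `s_0 = sqrt(1/N)`, `s_k = sqrt(2/N)` for `k > 0`.
#'
#' @param x numeric vector.
#' @return numeric vector of DCT-II coefficients, same length as `x`.
#' @export
dct_ii <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(x)
  v <- c(x[seq(1L, n, 2L)], rev(x[seq(2L, n, 2L)]))
  vf <- .fft_any(as.complex(v))
  k <- 0:(n - 1)
  coef <- Re(vf * exp(-1i * pi * k / (2 * n)))
  coef * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' Orthonormal type-III (inverse) discrete cosine transform
#'
#' Exact inverse of [dct_ii()].
#'
#' @param coef numeric vector of orthonormal DCT-II coefficients.
#' @return reconstructed signal, same length as `coef`.
#' @export
dct_iii <- function(coef) {
  n <- length(coef)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(coef)
  unnorm <- coef / c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  k <- 1:(n - 1)
  vf <- complex(length.out = n)
  vf[1] <- unnorm[1]
  vf[k + 1] <- exp(1i * pi * k / (2 * n)) * (unnorm[k + 1] - 1i * unnorm[n - k + 1])
  v <- Re(.fft_any(vf, inverse = TRUE)) / n
  x <- numeric(n)
  nh <- ceiling(n / 2)
  x[seq(1L, n, 2L)] <- v[1:nh]
  x[seq(2L, n, 2L)] <- rev(v[(nh + 1L):n])
  x
}
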