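# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; module- and
#' animal-level streams are split off deterministically with a multiplicative
#' hash so that changing one stage never perturbs another.
#'
#' @param seed master integer seed
#' @param k stream index (any non-negative integer)
#' @return an integer seed in `[0, 2^31 - 2]`
#' @keywords internal
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(k) + 1) * 16807
  as.integer(s %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthesize a real-valued noise series with a prescribed one-sided PSD.
# psd_fun(f) must return power spectral density in units^2/Hz for f > 0.
# Uses direct frequency-domain synthesis (one inverse FFT); length is padded
# to a fast FFT size and truncated, which is harmless for stationary noise.
colored_noise <- function(n, fs, psd_fun) {
  if (n < 2) return(numeric(n))
  m <- stats::nextn(n, c(2L, 3L, 5L))
  f <- (1:(m / 2)) * fs / m
  s <- psd_fun(f)
  s[!is.finite(s) | s < 0] <- 0
  # E|X_k|^2 = m * fs * S(f_k) / 2 for the interior bins of a length-m DFT
  amp <- sqrt(m * fs * s / 2)
  half <- length(f)
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) / sqrt(2)
  xk <- complex(length.out = m)
  xk[2:(half + 1)] <- amp * z
  xk[m / 2 + 1] <- complex(real = Re(xk[m / 2 + 1]) * sqrt(2), imaginary = 0)
  xk[m:(m / 2 + 2)] <- Conj(xk[2:(m / 2)])
  x <- Re(stats::fft(xk, inverse = TRUE)) / m
  x[seq_len(n)]
}

# Band-limited white noise on [f_lo, f_hi] with unit RMS, via spectral synthesis.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  stopifnot(f_hi > f_lo, f_hi <= fs / 2)
  x <- colored_noise(n, fs, function(f) as.numeric(f >= f_lo & f <= f_hi))
  x / stats::sd(x)
}
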