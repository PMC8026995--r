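#' One-sided power spectral density
#'
#' Segment-averaged periodogram (Welch's method). With `n_segments = 1` the
#' plain periodogram of the demeaned series is returned and the one-sided
#' spectrum satisfies Parseval's identity exactly: `sum(power) * df` equals
#' the population variance. With more segments, 50%-overlapping Hann-tapered
#' segments are averaged, trading frequency resolution for variance
#' reduction.
#'
#' @param series A [voltage_series()] or numeric vector.
#' @param n_segments Number of segments (default 8); each segment is demeaned
#'   before tapering.
#' @param sampling_rate Used when `series` is a bare vector.
#' @return A data frame with columns `freq` (Hz, in `(0, Nyquist]`) and
#'   `power` (uV^2/Hz).
#' @export
power_spectrum <- function(series, n_segments = 8L, sampling_rate = 1) {
  series <- as_voltage_series(series, sampling_rate)
  x <- series$samples
  fs <- series$sampling_rate
  N <- length(x)
  if (N < 64) stop("power_spectrum needs at least 64 samples, have ", N)
  n_segments <- max(1L, as.integer(n_segments))
  if (n_segments == 1L) {
    x <- x - mean(x)
    X <- stats::fft(x)
    nf <- N %/% 2
    pw <- 2 * Mod(X[2:(nf + 1)])^2 / (N * fs)
    if (N %% 2 == 0) pw[nf] <- pw[nf] / 2
    return(data.frame(freq = (1:nf) * fs / N, power = pw))
  }
  L <- floor(2 * N / (n_segments + 1))
  if (L < 16) stop("too many segments for series length")
  step <- max(1L, L %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hann
  U <- sum(w^2)
  starts <- seq(1L, N - L + 1L, by = step)
  nf <- L %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- 2 * Mod(X[2:(nf + 1)])^2 / (U * fs)
    if (L %% 2 == 0) p[nf] <- p[nf] / 2
    acc <- acc + p
  }
  data.frame(freq = (1:nf) * fs / L, power = acc / length(starts))
}

#' Spectral signature (1/f exponent) of a voltage series
#'
#' The spectral signature `beta` is the negated ordinary-least-squares slope
#' of log10 power versus log10 frequency: `beta = 0` for white noise,
#' `beta = 1` for pink (1/f) noise, `beta = 2` for Brownian noise. By default
#' the fit excludes the 3 lowest nonzero frequency bins (distorted by
#' detrending) and the top octave (taper roll-off).
#'
#' @param series A [voltage_series()] or numeric vector.
#' @param fit_freq_range Optional `c(f_lo, f_hi)` in Hz restricting the fit.
#' @param n_segments Segments for [power_spectrum()] (default 8).
#' @param sampling_rate Used when `series` is a bare vector.
#' @return An object of class `spectral_fit`: a list with `beta`,
#'   `intercept`, `stderr_beta`, `fit_freq_range`, `n_freqs_used`.
#' @examples
#' x <- cumsum(rnorm(2048))            # Brownian: beta near 2
#' spectral_signature(x)$beta
#' @export
spectral_signature <- function(series, fit_freq_range = NULL,
                               n_segments = 8L, sampling_rate = 1) {
  series <- as_voltage_series(series, sampling_rate)
  if (length(series$samples) < 256)
    stop("spectral_signature needs at least 256 samples")
  ps <- power_spectrum(series, n_segments = n_segments)
  f <- ps$freq; p <- ps$power
  if (is.null(fit_freq_range)) {
    keep <- seq_along(f) > 3 & f <= max(f) / 2
  } else {
    keep <- f >= fit_freq_range[1] & f <= fit_freq_range[2]
  }
  keep <- keep & p > 0
  if (sum(keep) < 8)
    stop("fewer than 8 frequency bins in the fit range")
  lf <- log10(f[keep]); lp <- log10(p[keep])
  cf <- ols_line(lf, lp)
  res <- lp - (cf[1] + cf[2] * lf)
  n <- length(lf)
  se <- sqrt(sum(res^2) / (n - 2) / sum((lf - mean(lf))^2))
  structure(list(beta = -cf[2], intercept = cf[1], stderr_beta = se,
                 fit_freq_range = range(f[keep]), n_freqs_used = n),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> beta = %.4f (se %.4f), %d bins over [%.4g, %.4g] Hz\n",
              x$beta, x$stderr_beta, x$n_freqs_used,
              x$fit_freq_range[1], x$fit_freq_range[2]))
  invisible(x)
}
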