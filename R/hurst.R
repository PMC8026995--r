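#' Rescaled-range statistic of a block
#'
#' Range of the mean-adjusted cumulative sum divided by the block standard
#' deviation (population convention, divide by n).
#'
#' @param block Numeric vector, length >= 2, nonzero variance.
#' @return Nonnegative scalar R/S value.
#' @examples
#' rs_statistic(c(1, -1))   # = 1
#' @export
rs_statistic <- function(block) {
  n <- length(block)
  if (n < 2) stop("rs_statistic needs a block of length >= 2")
  y <- block - mean(block)
  s <- sqrt(sum(y^2) / n)
  if (s <= 0) stop("rs_statistic undefined for zero-variance block")
  z <- cumsum(y)
  (max(z) - min(z)) / s
}

#' Expected rescaled range of i.i.d. data (Anis-Lloyd with finite-size term)
#'
#' The small-sample analytic expectation of the R/S statistic for independent
#' Gaussian data, using the exact gamma-function form for `n <= 340` and the
#' Stirling asymptote above, with the `(n - 1/2)/n` finite-size prefactor.
#' This is the basis of both the corrected R/S estimator and the theoretical
#' Hurst exponent.
#'
#' @param n Vector of block sizes (>= 2).
#' @return Vector of expected R/S values.
#' @export
expected_rs <- function(n) {
  vapply(as.integer(n), function(ni) {
    if (ni < 2) stop("expected_rs needs n >= 2")
    K <- ((ni - 1):1) / (1:(ni - 1))
    ratio <- (ni - 0.5) / ni * sum(sqrt(K))
    if (ni > 340) ratio / sqrt(0.5 * pi * ni)
    else gamma(0.5 * (ni - 1)) * ratio / (gamma(0.5 * ni) * sqrt(pi))
  }, numeric(1))
}

#' Default R/S block sizes for a series of length N
#'
#' The classical divisor scheme: the analysis length `opt_n` is the value in
#' `[0.99 N, N]` admitting the most divisors between `min_block` and
#' `opt_n / 2`; those divisors are the block sizes, so every block size tiles
#' the (trimmed) series exactly.
#'
#' @param n Series length.
#' @param min_block Smallest block size (default 50).
#' @return List with `block_sizes` (increasing integers) and `opt_n`.
#' @export
default_block_sizes <- function(n, min_block = 50L) {
  divisors <- function(k) {
    cand <- min_block:max(min_block, floor(k / 2))
    cand[k %% cand == 0]
  }
  n0 <- min(floor(0.99 * n), n - 1)
  best_n <- n0; best_d <- divisors(n0)
  for (k in (n0 + 1):n) {
    dk <- divisors(k)
    if (length(dk) > length(best_d)) { best_n <- k; best_d <- dk }
  }
  list(block_sizes = as.integer(best_d), opt_n = as.integer(best_n))
}

# Mean R/S over the contiguous non-overlapping blocks of one size.
mean_rs <- function(x, size) {
  m <- length(x) %/% size
  if (m < 1) stop("block size exceeds series length")
  vals <- vapply(seq_len(m), function(i)
    rs_statistic(x[((i - 1) * size + 1):(i * size)]), numeric(1))
  mean(vals)
}

#' Rescaled-range Hurst exponent family
#'
#' Computes the five R/S-based Hurst estimates reported together in classical
#' rescaled-range analysis:
#' \describe{
#'   \item{h_simple}{slope of log2 mean R/S across the two largest dyadic
#'     block sizes.}
#'   \item{h_empirical}{OLS slope of log10 mean R/S vs log10 block size over
#'     all block sizes.}
#'   \item{h_corrected_rs}{the Anis-Lloyd-corrected regression: slope of
#'     log10(R/S - E\[R/S\] + sqrt(pi n / 2)) vs log10 n, which removes the
#'     small-sample bias of the plain statistic.}
#'   \item{h_theoretical}{slope of log10 E\[R/S\] vs log10 n over the same
#'     block sizes — a function of the block sizes only, approaching 0.5 as
#'     all blocks grow.}
#'   \item{h_corrected_empirical}{`h_empirical - (h_theoretical - 1/2)`, the
#'     shift-by-expectation convention.}
#' }
#' When `block_sizes` is `NULL` the divisor scheme of
#' [default_block_sizes()] is used and the series is trimmed to `opt_n`;
#' user-supplied block sizes use `floor(N / n)` complete blocks per size.
#'
#' @param series A [voltage_series()] or numeric vector (length >= 256 for
#'   defaults; shorter series are accepted with explicit `block_sizes`).
#' @param block_sizes Optional increasing integer vector (>= 4 sizes, each
#'   >= 8).
#' @return Object of class `hurst_estimates`: list with the five exponents,
#'   `block_sizes`, `mean_rs`, `expected_rs`, `opt_n`, and the `sd_convention`
#'   used ("population").
#' @export
hurst_family <- function(series, block_sizes = NULL) {
  series <- as_voltage_series(series)
  x <- series$samples
  N <- length(x)
  if (is.null(block_sizes)) {
    if (N < 256) stop("hurst_family needs >= 256 samples for default blocks")
    db <- default_block_sizes(N)
    block_sizes <- db$block_sizes
    x <- x[seq_len(db$opt_n)]
    opt_n <- db$opt_n
  } else {
    block_sizes <- sort(as.integer(block_sizes))
    opt_n <- N
  }
  if (length(block_sizes) < 4)
    stop("hurst_family needs at least 4 block sizes")
  if (min(block_sizes) < 8 || max(block_sizes) > length(x))
    stop("block sizes must lie in [8, series length]")
  rs <- vapply(block_sizes, function(s) mean_rs(x, s), numeric(1))
  ers <- expected_rs(block_sizes)
  ln <- log10(block_sizes)
  h_empirical <- ols_line(ln, log10(rs))[2]
  h_theoretical <- ols_line(ln, log10(ers))[2]
  corrected <- rs - ers + sqrt(0.5 * pi * block_sizes)
  if (any(corrected <= 0))
    stop("corrected R/S non-positive; series too far from scaling regime")
  h_corrected_rs <- ols_line(ln, log10(corrected))[2]
  h_corrected_empirical <- h_empirical - (h_theoretical - 0.5)
  # simple estimate: two largest dyadic scales
  n1 <- 2^floor(log2(length(x) / 2))
  n2 <- n1 / 2
  h_simple <- log2(mean_rs(x, n1) / mean_rs(x, n2))
  structure(list(h_simple = h_simple,
                 h_corrected_rs = h_corrected_rs,
                 h_empirical = h_empirical,
                 h_corrected_empirical = h_corrected_empirical,
                 h_theoretical = h_theoretical,
                 block_sizes = block_sizes,
                 mean_rs = rs, expected_rs = ers, opt_n = opt_n,
                 sd_convention = "population"),
            class = "hurst_estimates")
}

#' @export
print.hurst_estimates <- function(x, ...) {
  cat("<hurst_estimates>\n")
  cat(sprintf("  simple %.4f | corrected R/S %.4f | empirical %.4f | corrected empirical %.4f | theoretical %.4f\n",
              x$h_simple, x$h_corrected_rs, x$h_empirical,
              x$h_corrected_empirical, x$h_theoretical))
  cat(sprintf("  %d block sizes in [%d, %d] (opt_n = %d, %s sd)\n",
              length(x$block_sizes), min(x$block_sizes), max(x$block_sizes),
              x$opt_n, x$sd_convention))
  invisible(x)
}

#' Detrended fluctuation analysis exponent
#'
#' Slope of the log-log fluctuation function: the series is integrated
#' (cumulative sum of deviations from the mean), split into non-overlapping
#' windows of each scale, linearly detrended per window, and the RMS residual
#' regressed on scale. `alpha = 0.5` for white noise, `1.5` for its
#' integral; `alpha = H` for stationary fractional noise.
#'
#' @param series A [voltage_series()] or numeric vector, length >= 256.
#' @param scales Optional increasing integer vector of window sizes (>= 4
#'   scales). Default: 12 log-spaced scales from 8 to N/8.
#' @return Scalar DFA exponent, with the scales and fluctuation function as
#'   attributes.
#' @export
dfa_alpha <- function(series, scales = NULL) {
  series <- as_voltage_series(series)
  x <- series$samples
  N <- length(x)
  if (N < 256) stop("dfa_alpha needs at least 256 samples")
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(8), log(N / 8), length.out = 12))))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4) stop("dfa_alpha needs at least 4 scales")
  y <- cumsum(x - mean(x))
  fluct <- vapply(scales, function(s) {
    m <- N %/% s
    t <- seq_len(s)
    ssq <- 0
    for (i in seq_len(m)) {
      seg <- y[((i - 1) * s + 1):(i * s)]
      cf <- ols_line(t, seg)
      ssq <- ssq + sum((seg - cf[1] - cf[2] * t)^2)
    }
    sqrt(ssq / (m * s))
  }, numeric(1))
  a <- ols_line(log10(scales), log10(fluct))[2]
  structure(a, scales = scales, fluctuation = fluct)
}
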