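#' Approximate entropy (ApEn)
#'
#' Pincus's regularity statistic `phi^m(r) - phi^(m+1)(r)` with Chebyshev
#' (max-coordinate) distance and self-matches included. Low values indicate
#' a regular, deterministic series; values near `log` of the effective state
#' count indicate randomness. The tolerance `r` is by default a fraction of
#' the series standard deviation, making the statistic invariant under
#' affine rescaling of the signal.
#'
#' @param series A [voltage_series()] or numeric vector, length >= m + 2.
#' @param m Template length (default 2).
#' @param r Match tolerance (default 0.2). Interpreted per `r_type`.
#' @param r_type `"sd"` (default, `r` is a fraction of the sample SD) or
#'   `"absolute"` (`r` is in signal units).
#' @return Nonnegative scalar with attributes `m`, `r`, `r_absolute`.
#' @export
approximate_entropy <- function(series, m = 2L, r = 0.2,
                                r_type = c("sd", "absolute")) {
  series <- as_voltage_series(series)
  r_type <- match.arg(r_type)
  x <- series$samples
  N <- length(x)
  m <- as.integer(m)
  if (m < 1 || r <= 0) stop("need m >= 1 and r > 0")
  if (N < m + 2) stop("series too short: need N >= m + 2")
  r_abs <- if (r_type == "sd") {
    s <- stats::sd(x)
    if (s <= 0) stop("zero-SD series: relative tolerance undefined (use r_type = 'absolute')")
    r * s
  } else r
  val <- cf_apen_phi(x, m, r_abs) - cf_apen_phi(x, m + 1L, r_abs)
  structure(max(val, 0), m = m, r = r, r_absolute = r_abs)
}

#' Sample entropy (SampEn)
#'
#' Richman-Moorman's `-log(A/B)`: A counts Chebyshev-matching template pairs
#' of length m+1 and B of length m, self-matches excluded, templates indexed
#' so that every length-m template can be extended. Less length-dependent
#' than [approximate_entropy()] and zero for strictly repeating signals.
#' When no length-(m+1) pair matches (`A = 0`) the statistic is undefined
#' and `Inf` is returned with attribute `flagged = TRUE`, so that sweep
#' aggregation can drop the cell rather than abort.
#'
#' @inheritParams approximate_entropy
#' @return Nonnegative scalar (possibly `Inf`, flagged) with attributes `m`,
#'   `r`, `r_absolute`, `flagged`.
#' @export
sample_entropy <- function(series, m = 2L, r = 0.2,
                           r_type = c("sd", "absolute")) {
  series <- as_voltage_series(series)
  r_type <- match.arg(r_type)
  x <- series$samples
  N <- length(x)
  m <- as.integer(m)
  if (m < 1 || r <= 0) stop("need m >= 1 and r > 0")
  if (N < m + 2) stop("series too short: need N >= m + 2")
  r_abs <- if (r_type == "sd") {
    s <- stats::sd(x)
    if (s <= 0) stop("zero-SD series: relative tolerance undefined (use r_type = 'absolute')")
    r * s
  } else r
  cnt <- cf_sampen_counts(x, m, r_abs)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0) stop("no length-m template matches at this tolerance; increase r")
  if (A == 0)
    return(structure(Inf, m = m, r = r, r_absolute = r_abs, flagged = TRUE))
  structure(-log(A / B), m = m, r = r, r_absolute = r_abs, flagged = FALSE)
}
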