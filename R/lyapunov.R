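#' Largest Lyapunov exponent by mean neighbour divergence
#'
#' Rosenstein-style estimator: for every attractor point the nearest
#' Euclidean neighbour outside the Theiler window is tracked forward, and
#' the divergence curve — the mean natural-log distance after k steps over
#' all valid pairs — is regressed on k over `fit_range`. The slope is the
#' largest Lyapunov exponent per sample; multiplying by the sampling rate
#' gives the per-second value. Positive values indicate exponential
#' trajectory separation (chaos), negative values convergence (stable,
#' strongly mean-reverting dynamics).
#'
#' @param attractor An [embed_series()] result (or numeric matrix of points
#'   in rows; supply `sampling_rate` then).
#' @param theiler_window Temporal exclusion window in samples (default: the
#'   embedding delay if known, else 1).
#' @param n_steps Length of the divergence curve (default 30).
#' @param fit_range Integer pair of divergence steps for the slope fit
#'   (default `c(1, 10)`).
#' @param sampling_rate Override for plain-matrix input.
#' @return Object of class `lyapunov_estimate`: list with
#'   `lambda_per_sample`, `lambda_per_second`, `divergence_curve` (steps
#'   0..n_steps), `n_pairs`, `fit_range`, `theiler_window`.
#' @examples
#' x <- numeric(3000); x[1] <- 0.2
#' for (i in 2:3000) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])  # logistic, r = 4
#' a <- embed_series(x, dim = 1, delay = 1)
#' max_lyapunov(a, theiler_window = 1, fit_range = c(1, 7))$lambda_per_sample
#' # close to log(2)
#' @export
max_lyapunov <- function(attractor, theiler_window = NULL, n_steps = 30L,
                         fit_range = c(1L, 10L), sampling_rate = NULL) {
  a <- unclass(attractor)
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (is.null(sampling_rate))
    sampling_rate <- attr(attractor, "sampling_rate") %||% 1
  if (is.null(theiler_window))
    theiler_window <- attr(attractor, "delay") %||% 1L
  M <- nrow(a)
  if (M < 200) stop("max_lyapunov needs at least 200 attractor points")
  n_steps <- as.integer(n_steps)
  fit_range <- as.integer(fit_range)
  if (fit_range[1] < 1 || fit_range[2] > n_steps || fit_range[1] >= fit_range[2])
    stop("fit_range must lie within [1, n_steps]")
  dv <- cf_divergence(a, as.integer(theiler_window), n_steps)
  curve <- dv$curve
  np <- dv$n_pairs
  if (np[1] < 10)
    stop("fewer than 10 valid neighbour pairs; increase series length or reduce theiler_window")
  ks <- fit_range[1]:fit_range[2]
  ok <- is.finite(curve[ks + 1L])
  if (sum(ok) < 2) stop("divergence curve undefined over fit_range")
  slope <- ols_line(ks[ok], curve[ks + 1L][ok])[2]
  structure(list(lambda_per_sample = slope,
                 lambda_per_second = slope * sampling_rate,
                 divergence_curve = curve,
                 n_pairs = np,
                 fit_range = fit_range,
                 theiler_window = as.integer(theiler_window),
                 sampling_rate = sampling_rate),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate> lambda = %.4f per sample (%.4f per s), fit over steps %d..%d, %d pairs\n",
              x$lambda_per_sample, x$lambda_per_second,
              x$fit_range[1], x$fit_range[2], x$n_pairs[1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
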