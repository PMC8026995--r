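#' Aggregate per-series measures into a temperature profile
#'
#' Collapses a per-series measure table (one row per recording, as returned
#' by [run_measure()]) into one row per temperature with the replicate mean,
#' sample SD, and replicate count for every measure column. Non-finite
#' values (e.g. the flagged sample-entropy sentinel) are excluded pointwise
#' and the exclusion count recorded.
#'
#' @param measures Data frame with a `temperature` column and numeric
#'   measure columns.
#' @param columns Measure columns to aggregate (default: all numeric columns
#'   other than temperature/replicate bookkeeping).
#' @return Object of class `sweep_profile`: a data frame with columns
#'   `temperature` and, per measure `<x>`, `<x>_mean`, `<x>_sd`, `<x>_n`;
#'   attribute `n_excluded` counts dropped cells.
#' @export
build_profile <- function(measures, columns = NULL) {
  stopifnot(is.data.frame(measures), "temperature" %in% names(measures))
  if (is.null(columns)) {
    skip <- c("temperature", "replicate_id", "label")
    columns <- setdiff(names(measures)[vapply(measures, is.numeric,
                                              logical(1))], skip)
  }
  temps <- sort(unique(measures$temperature))
  if (length(temps) < 4)
    stop("build_profile needs >= 4 distinct temperatures (resonance fit underdetermined)")
  n_excluded <- 0L
  out <- data.frame(temperature = temps)
  for (cl in columns) {
    mn <- sdv <- nn <- numeric(length(temps))
    for (i in seq_along(temps)) {
      v <- measures[[cl]][measures$temperature == temps[i]]
      bad <- !is.finite(v)
      n_excluded <- n_excluded + sum(bad)
      v <- v[!bad]
      nn[i] <- length(v)
      mn[i] <- if (length(v)) mean(v) else NA_real_
      sdv[i] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    out[[paste0(cl, "_mean")]] <- mn
    out[[paste0(cl, "_sd")]] <- sdv
    out[[paste0(cl, "_n")]] <- as.integer(nn)
  }
  structure(out, class = c("sweep_profile", "data.frame"),
            n_excluded = n_excluded, measures = columns)
}

#' Guarded elementwise reciprocal of a measure profile
#'
#' `1 / max(|v|, floor)` with the input's sign retained, or negated when
#' `negate = TRUE` — the convention for the largest Lyapunov exponent, whose
#' negated reciprocal turns stable (negative) dynamics into a positive peak.
#' Values floored to avoid division blow-up are flagged in the `"flagged"`
#' attribute.
#'
#' @param values Numeric vector.
#' @param floor Positive guard (default 1e-6).
#' @param negate Apply the `-1/v` convention (default `FALSE`).
#' @return Numeric vector with attribute `flagged` (logical vector).
#' @examples
#' invert_measure(c(2, 4))                      # 0.5 0.25
#' invert_measure(c(-14.04, -15.01), negate = TRUE)  # positive peaks
#' @export
invert_measure <- function(values, floor = 1e-6, negate = FALSE) {
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0")
  a <- abs(values)
  flag <- is.finite(values) & a < floor
  sgn <- ifelse(values < 0, -1, 1)       # sign(0) treated as +1
  out <- sgn / pmax(a, floor)
  out[!is.finite(values)] <- NA_real_
  if (negate) out <- -out
  structure(out, flagged = flag, floor = floor, negate = negate)
}

# Deterministic multi-start Lorentzian least squares via minpack.lm.
fit_lorentz_nls <- function(x, y, w, n_starts = 5L) {
  pk <- which.max(y)
  base0 <- min(y)
  amp0 <- max(y[pk] - base0, .Machine$double.eps)
  above <- x[y > base0 + amp0 / 2]
  span <- diff(range(x))
  g0 <- max(diff(range(above)) / 2, span / 20)
  jit <- list(c(0, 0, 0), c(0.1, 0.3, 0.25), c(-0.1, -0.3, 0.5),
              c(0.2, 0.6, -0.3), c(-0.2, -0.6, 1.0))
  best <- NULL
  errs <- character(0)
  for (j in seq_len(min(n_starts, length(jit)))) {
    st <- list(baseline = base0,
               amplitude = amp0 * (1 + jit[[j]][1]),
               t_c = x[pk] + jit[[j]][2] * span / 10,
               gam = g0 * (1 + jit[[j]][3]))
    args <- list(
      y ~ baseline + amplitude * gam^2 / ((x - t_c)^2 + gam^2),
      start = st,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14),
      data = data.frame(x = x, y = y))
    if (!is.null(w)) args$weights <- w
    fit <- tryCatch(
      do.call(minpack.lm::nlsLM, args),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    stop("Lorentzian fit failed for all starts: ",
         paste(unique(errs), collapse = "; "))
  best
}

#' Fit a Lorentzian resonance curve
#'
#' Least-squares fit of the four-parameter Lorentzian
#' `y(T) = baseline + amplitude * gamma^2 / ((T - t_c)^2 + gamma^2)`,
#' where `gamma` is the half-width at half-maximum (HWHM) of the peak above
#' baseline. Initial values are taken from the data (peak location, minimum,
#' half-maximum span) and refined by Levenberg-Marquardt from five
#' deterministically jittered starts, keeping the best residual. This is the
#' model used to localise the critical temperature from inverse dynamic
#' measures.
#'
#' @param x Numeric vector of temperatures (degC), >= 4 points.
#' @param y Numeric vector of measure values (finite).
#' @param weights Optional nonnegative fit weights.
#' @return Object of class `lorentz_fit` with coefficients `t_c`,
#'   `half_width`, `amplitude`, `baseline`; fields `stderr`, `r_squared`,
#'   `y_error` (RMS residual after range-normalising y to \[0, 1\]), `fwhm`,
#'   `fitted`, `residuals`, `data`, `weights`, `channel`.
#' @examples
#' Tg <- seq(30, 43, length.out = 15)
#' y <- 0.2 + 1 * 2^2 / ((Tg - 36.6)^2 + 2^2)
#' coef(lorentz_fit(Tg, y))
#' @export
lorentz_fit <- function(x, y, weights = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(weights)) ok <- ok & is.finite(weights) & weights >= 0
  x <- x[ok]; y <- y[ok]
  w <- if (is.null(weights)) NULL else as.numeric(weights)[ok]
  if (length(x) < 4) stop("lorentz_fit needs at least 4 finite points")
  if (stats::var(y) == 0) stop("lorentz_fit undefined for constant y")
  fit <- fit_lorentz_nls(x, y, w)
  cf <- stats::coef(fit)
  cf["gam"] <- abs(cf["gam"])
  res <- y - (cf["baseline"] + cf["amplitude"] * cf["gam"]^2 /
                ((x - cf["t_c"])^2 + cf["gam"]^2))
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  yrange <- diff(range(y))
  y_error <- sqrt(mean((res / yrange)^2))
  se <- tryCatch({
    s <- sqrt(diag(stats::vcov(fit)))
    stats::setNames(s[c("t_c", "gam", "amplitude", "baseline")],
                    c("t_c", "half_width", "amplitude", "baseline"))
  }, error = function(e)
    stats::setNames(rep(NA_real_, 4),
                    c("t_c", "half_width", "amplitude", "baseline")))
  if (r2 < 0.5)
    warning(sprintf("weak resonance: R^2 = %.3f (no clear peak in this channel)", r2))
  structure(list(
    coefficients = c(t_c = unname(cf["t_c"]),
                     half_width = unname(cf["gam"]),
                     amplitude = unname(cf["amplitude"]),
                     baseline = unname(cf["baseline"])),
    stderr = se, r_squared = r2, y_error = y_error,
    fwhm = 2 * unname(cf["gam"]),
    fitted = y - res, residuals = res,
    data = data.frame(x = x, y = y),
    weights = w, n_starts = 5L,
    convention = "half_width is HWHM of the peak above baseline",
    channel = NA_character_),
    class = "lorentz_fit")
}

#' Localise the critical temperature from one measure channel
#'
#' Composes the channel transform with [lorentz_fit()]: the inverse of
#' approximate or sample entropy (`1/S_a`, `1/S_s`), the negated inverse of
#' the largest Lyapunov exponent (`-1/Lambda`), or the spectral signature
#' itself (which peaks at the critical temperature without inversion). The
#' fitted `t_c` is the channel's critical-temperature estimate.
#'
#' @param profile A [build_profile()] result containing the relevant
#'   `<measure>_mean` column.
#' @param channel One of `"s_s"`, `"s_a"`, `"lambda"`, `"beta"`.
#' @param weights `"none"` (default) or `"inverse_variance"` (weights
#'   `n / sd^2` from the replicate spread; temperatures lacking an SD get
#'   the median weight).
#' @param floor Inversion guard passed to [invert_measure()].
#' @return A [lorentz_fit()] object with `channel` metadata set.
#' @export
localize_tc <- function(profile,
                        channel = c("s_s", "s_a", "lambda", "beta"),
                        weights = c("none", "inverse_variance"),
                        floor = 1e-6) {
  stopifnot(inherits(profile, "sweep_profile"))
  channel <- match.arg(channel)
  weights <- match.arg(weights)
  colname <- paste0(channel, "_mean")
  if (!colname %in% names(profile))
    stop("profile lacks column ", colname)
  v <- profile[[colname]]
  y <- switch(channel,
              s_s = invert_measure(v, floor),
              s_a = invert_measure(v, floor),
              lambda = invert_measure(v, floor, negate = TRUE),
              beta = v)
  w <- NULL
  if (weights == "inverse_variance") {
    sdc <- profile[[paste0(channel, "_sd")]]
    nc <- profile[[paste0(channel, "_n")]]
    w <- nc / sdc^2
    w[!is.finite(w)] <- stats::median(w[is.finite(w)])
  }
  fit <- lorentz_fit(profile$temperature, as.numeric(y), weights = w)
  fit$channel <- switch(channel, s_s = "1/S_s", s_a = "1/S_a",
                        lambda = "-1/Lambda", beta = "beta")
  fit$inversion_floor <- if (channel == "beta") NA_real_ else floor
  fit$weighting <- weights
  fit
}

#' Cross-measure proportionality over the temperature grid
#'
#' Pearson correlations among the criticality channels `beta`, `1/S_a`,
#' `1/S_s`, and `-1/Lambda` evaluated on the temperature profile. The
#' empirical signature of a common critical mechanism is that all channels
#' rise and fall together; the report flags support when every pairwise
#' correlation reaches `threshold`.
#'
#' @param profile A [build_profile()] result (>= 5 temperatures).
#' @param threshold Support threshold on each pairwise correlation
#'   (default 0.7).
#' @param floor Inversion guard.
#' @return Object of class `proportionality_report`: list with
#'   `correlations` (matrix), `supported` (logical), `threshold`, `flagged`
#'   (channels with undefined correlations).
#' @export
proportionality_check <- function(profile, threshold = 0.7, floor = 1e-6) {
  stopifnot(inherits(profile, "sweep_profile"))
  if (nrow(profile) < 5)
    stop("proportionality_check needs >= 5 temperatures")
  has <- function(cl) cl %in% names(profile) &&
    any(is.finite(profile[[cl]]))          # skip unmeasured channels
  chans <- list()
  if (has("beta_mean"))
    chans[["beta"]] <- profile$beta_mean
  if (has("s_a_mean"))
    chans[["1/S_a"]] <- as.numeric(invert_measure(profile$s_a_mean, floor))
  if (has("s_s_mean"))
    chans[["1/S_s"]] <- as.numeric(invert_measure(profile$s_s_mean, floor))
  if (has("lambda_mean"))
    chans[["-1/Lambda"]] <- as.numeric(invert_measure(profile$lambda_mean,
                                                      floor, negate = TRUE))
  if (length(chans) < 2)
    stop("profile contains fewer than 2 proportionality channels")
  m <- do.call(cbind, chans)
  flagged <- colnames(m)[apply(m, 2, function(v)
    stats::var(v, na.rm = TRUE) == 0 || all(!is.finite(v)))]
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  off <- cm[upper.tri(cm)]
  supported <- all(is.finite(off)) && all(off >= threshold) &&
    length(flagged) == 0
  structure(list(correlations = cm, supported = supported,
                 threshold = threshold, flagged = flagged),
            class = "proportionality_report")
}

#' @export
print.proportionality_report <- function(x, ...) {
  cat("<proportionality_report>\n")
  print(round(x$correlations, 3))
  cat(sprintf("  all pairwise correlations >= %.2f: %s\n", x$threshold,
              if (x$supported) "yes" else "no"))
  if (length(x$flagged))
    cat("  flagged (undefined):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
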