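#' Embedding delay from the autocorrelation function
#'
#' Smallest lag at which the sample autocorrelation first falls below `1/e`
#' (default) or below zero (`rule = "zero"`). If the threshold is never
#' reached within `max_lag`, `max_lag` is returned with a warning.
#'
#' @param series A [voltage_series()] or numeric vector.
#' @param max_lag Largest lag considered (must be < N/2; default
#'   `min(100, N %/% 4)`).
#' @param rule `"1/e"` (default) or `"zero"`.
#' @return Positive integer delay in samples.
#' @export
acf_delay <- function(series, max_lag = NULL, rule = c("1/e", "zero")) {
  series <- as_voltage_series(series)
  rule <- match.arg(rule)
  x <- series$samples
  N <- length(x)
  if (stats::var(x) <= 0) stop("acf_delay undefined for zero-variance series")
  if (is.null(max_lag)) max_lag <- min(100L, N %/% 4L)
  max_lag <- as.integer(max_lag)
  if (max_lag >= N / 2) stop("max_lag must be smaller than N/2")
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  thr <- if (rule == "1/e") exp(-1) else 0
  hit <- which(ac < thr)
  if (length(hit) == 0) {
    warning("autocorrelation never fell below threshold; returning max_lag")
    return(max_lag)
  }
  as.integer(hit[1])
}

# Average mutual information curve (histogram estimator, natural log).
ami_curve <- function(x, max_lag, n_bins) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("ami undefined for constant series")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  N <- length(x)
  vapply(seq_len(max_lag), function(tau) {
    a <- bin[1:(N - tau)]
    b <- bin[(tau + 1):N]
    joint <- table(factor(a, levels = 1:n_bins),
                   factor(b, levels = 1:n_bins)) / (N - tau)
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
}

#' Embedding delay from average mutual information
#'
#' Lag of the first strict local minimum of the histogram-based average
#' mutual information between the series and its lagged copy. If no local
#' minimum occurs below `max_lag`, falls back to [acf_delay()] with a
#' warning.
#'
#' @param series A [voltage_series()] or numeric vector (N >= 500
#'   recommended for the default 16 bins).
#' @param max_lag Largest lag scanned (default `min(100, N %/% 4)`).
#' @param n_bins Number of equal-width histogram bins (default 16).
#' @return Positive integer delay in samples; the AMI curve is attached as
#'   attribute `"ami"`.
#' @export
ami_delay <- function(series, max_lag = NULL, n_bins = 16L) {
  series <- as_voltage_series(series)
  x <- series$samples
  N <- length(x)
  if (is.null(max_lag)) max_lag <- min(100L, N %/% 4L)
  max_lag <- as.integer(max_lag)
  ami <- ami_curve(x, max_lag, as.integer(n_bins))
  # lag 0 AMI is the marginal entropy, always an upper bound on ami[1]
  for (k in seq_len(max_lag - 1L)) {
    left <- if (k == 1L) TRUE else ami[k] < ami[k - 1L]
    if (left && ami[k] < ami[k + 1L])
      return(structure(k, ami = ami))
  }
  warning("no local AMI minimum below max_lag; falling back to acf_delay")
  structure(acf_delay(series, max_lag = max_lag), ami = ami)
}

#' Delay-coordinate (Takens) embedding
#'
#' Builds the attractor matrix whose i-th row is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1) tau})`.
#'
#' @param series A [voltage_series()] or numeric vector.
#' @param dim Embedding dimension m (>= 1).
#' @param delay Delay tau in samples (>= 1).
#' @return Object of class `attractor`: a numeric matrix with
#'   `N - (m-1) tau` rows and attributes `delay`, `source_length`,
#'   `sampling_rate`.
#' @export
embed_series <- function(series, dim, delay) {
  series <- as_voltage_series(series)
  x <- series$samples
  N <- length(x)
  dim <- as.integer(dim); delay <- as.integer(delay)
  if (dim < 1 || delay < 1) stop("dim and delay must be >= 1")
  M <- N - (dim - 1L) * delay
  if (M < 2)
    stop(sprintf("series too short to embed: need >= %d samples, have %d",
                 (dim - 1L) * delay + 2L, N))
  a <- vapply(0:(dim - 1L), function(k) x[(1:M) + k * delay], numeric(M))
  a <- matrix(a, nrow = M)
  structure(a, class = "attractor", delay = delay, source_length = N,
            sampling_rate = series$sampling_rate)
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor> %d points in %d dimensions (delay %d, from %d samples)\n",
              nrow(x), ncol(x), attr(x, "delay"), attr(x, "source_length")))
  invisible(x)
}

#' Minimal embedding dimension by false nearest neighbours
#'
#' Kennel's criterion: for each candidate dimension the nearest neighbour of
#' every point (outside a Theiler exclusion window) is checked; a neighbour
#' is false if the extra coordinate gained in dimension d+1 inflates the
#' distance by more than `rtol`, or pushes it beyond `atol` times the
#' attractor size. The smallest dimension whose false-neighbour fraction
#' drops below `fnn_tol` is returned; `max_dim` with a warning otherwise
#' (as for stochastic series, which never embed).
#'
#' @param series A [voltage_series()] or numeric vector.
#' @param delay Embedding delay in samples.
#' @param max_dim Largest dimension tried (default 12).
#' @param theiler_window Temporal exclusion window (default `delay`).
#' @param rtol Distance-ratio threshold (default 10).
#' @param atol Attractor-size threshold (default 2).
#' @param fnn_tol Acceptable false-neighbour fraction (default 0.02).
#' @return Integer dimension; the per-dimension fractions are attached as
#'   attribute `"fnn"`.
#' @export
embedding_dimension <- function(series, delay, max_dim = 12L,
                                theiler_window = delay, rtol = 10,
                                atol = 2, fnn_tol = 0.02) {
  series <- as_voltage_series(series)
  x <- series$samples
  N <- length(x)
  delay <- as.integer(delay); max_dim <- as.integer(max_dim)
  if (N - (max_dim - 1L) * delay < 100)
    stop("insufficient points to test max_dim: need N - (max_dim-1)*delay >= 100")
  fr <- numeric(max_dim)
  for (d in seq_len(max_dim)) {
    fr[d] <- cf_fnn_fraction(x, delay, d, as.integer(theiler_window),
                             rtol, atol)
    if (is.finite(fr[d]) && fr[d] < fnn_tol)
      return(structure(d, fnn = fr[seq_len(d)]))
  }
  warning("false-neighbour fraction never fell below tolerance; returning max_dim")
  structure(max_dim, fnn = fr)
}

#' Shape anisotropy of a reconstructed attractor
#'
#' Eigen-decomposition of the centred second-moment (covariance) matrix of
#' the attractor point cloud. The sphericity — smallest over largest
#' eigenvalue — is 1 for an isotropic cloud and 0 for one collapsed onto a
#' lower-dimensional subspace, quantifying the loss of rotational symmetry
#' of the phase-space volume.
#'
#' @param attractor An [embed_series()] result (or plain numeric matrix of
#'   points in rows).
#' @return List with `sphericity` (in `[0, 1]`) and `extents` (eigenvalues,
#'   decreasing).
#' @export
sphericity <- function(attractor) {
  a <- unclass(attractor)
  if (!is.matrix(a)) stop("attractor must be a matrix of points")
  if (nrow(a) < ncol(a) + 1) stop("need at least dim + 1 points")
  cen <- sweep(a, 2, colMeans(a))
  if (max(abs(cen)) == 0) stop("degenerate attractor: all points identical")
  ev <- eigen(crossprod(cen) / nrow(a), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  list(sphericity = ev[length(ev)] / ev[1], extents = ev)
}
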