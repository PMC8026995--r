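#' Read a voltage recording from delimited text
#'
#' Series files are two-column delimited text (comma or tab, auto-detected):
#' time in seconds and voltage in microvolts, with an optional header line.
#' The sampling rate is inferred from the median time step; files whose time
#' steps deviate from the median by more than `jitter_tol` (relative) are
#' rejected as non-uniformly sampled.
#'
#' @param path Path to a series file.
#' @param temperature,replicate_id,label Optional metadata attached to the
#'   returned series (normally supplied via a sweep manifest, see
#'   [read_sweep()]).
#' @param jitter_tol Maximum allowed relative deviation of any time step from
#'   the median step (default 1%).
#' @return A [voltage_series()].
#' @seealso [write_series()], [read_sweep()]
#' @export
read_series <- function(path, temperature = NA_real_, replicate_id = 1L,
                        label = basename(path), jitter_tol = 0.01) {
  if (!file.exists(path)) stop("series file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    suppressWarnings(any(is.na(as.numeric(fields))))
  }
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("series file must have two columns (time, voltage): ",
                         path)
  tm <- suppressWarnings(as.numeric(df[[1]]))
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(tm) || anyNA(v))
    stop("non-numeric rows in series file: ", path)
  if (length(tm) < 2) stop("series too short (need >= 2 samples): ", path)
  dt <- diff(tm)
  med <- stats::median(dt)
  if (med <= 0) stop("non-increasing time column in ", path)
  if (any(abs(dt - med) > jitter_tol * med))
    stop(sprintf(
      "non-uniform sampling in %s: max step deviation %.3g%% of median step %.6g s (tolerance %.3g%%)",
      path, 100 * max(abs(dt - med)) / med, med, 100 * jitter_tol))
  voltage_series(v, sampling_rate = 1 / med, temperature = temperature,
                 replicate_id = replicate_id, label = label)
}

#' Write a voltage recording as delimited text
#'
#' @param series A [voltage_series()].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param digits Significant digits for the voltage column.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sep = ",", digits = 15) {
  stopifnot(inherits(series, "voltage_series"))
  n <- length(series$samples)
  tm <- (seq_len(n) - 1) / series$sampling_rate
  df <- data.frame(time_s = format(tm, digits = digits, trim = TRUE),
                   voltage_uV = format(series$samples, digits = digits,
                                       trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a temperature-sweep manifest and its series files
#'
#' The manifest is delimited text with columns `series_path`,
#' `temperature_C`, `replicate_id`. Paths are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param manifest Path to the manifest file.
#' @param ... Passed on to [read_series()].
#' @return A list of [voltage_series()] objects.
#' @export
read_sweep <- function(manifest, ...) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  first <- readLines(manifest, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(manifest, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("series_path", "temperature_C", "replicate_id")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty manifest: ", manifest)
  base <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$series_path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_series(p, temperature = df$temperature_C[i],
                replicate_id = df$replicate_id[i], ...)
  })
}

#' Detrend a voltage series
#'
#' Removes the mean, the global least-squares line, or a piecewise linear
#' trend (independent least-squares lines over contiguous non-overlapping
#' windows) — the standard pre-step before computing scaling and complexity
#' measures on drift-prone electrode recordings. In piecewise mode a trailing
#' partial window is detrended by extending the final full window's fitted
#' line.
#'
#' @param series A [voltage_series()] (or numeric vector, taken at 1 Hz).
#' @param mode One of `"mean"`, `"linear"` (default), `"piecewise_linear"`.
#' @param window_length Window length in samples for piecewise mode
#'   (default 500; must be >= 4, and the series at least twice as long).
#' @return A [voltage_series()] of identical length and sampling rate.
#' @examples
#' vs <- voltage_series(2 + 3 * seq(0, 1, length.out = 100), 4.1)
#' max(abs(detrend(vs, "linear")$samples)) < 1e-9
#' @export
detrend <- function(series, mode = c("linear", "mean", "piecewise_linear"),
                    window_length = 500L) {
  series <- as_voltage_series(series)
  mode <- match.arg(mode)
  x <- series$samples
  n <- length(x)
  if (mode == "mean") {
    out <- x - mean(x)
  } else if (mode == "linear") {
    t <- seq_len(n)
    cf <- ols_line(t, x)
    out <- x - (cf[1] + cf[2] * t)
  } else {
    window_length <- as.integer(window_length)
    if (window_length < 4)
      stop("piecewise_linear needs window_length >= 4")
    if (n < 2L * window_length)
      stop(sprintf("series too short for piecewise_linear: need >= %d samples, have %d",
                   2L * window_length, n))
    out <- numeric(n)
    n_full <- n %/% window_length
    cf <- c(0, 0); off <- 0L
    for (w in seq_len(n_full)) {
      idx <- ((w - 1L) * window_length + 1L):(w * window_length)
      t <- seq_along(idx)
      cf <- ols_line(t, x[idx])
      out[idx] <- x[idx] - (cf[1] + cf[2] * t)
      off <- idx[length(idx)]
    }
    if (off < n) {  # tail: extend the final full window's fitted line
      idx <- (off + 1L):n
      t <- window_length + seq_along(idx)
      out[idx] <- x[idx] - (cf[1] + cf[2] * t)
    }
  }
  series$samples <- out
  series
}
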