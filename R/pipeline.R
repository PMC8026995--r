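#' Measure every series of a sweep
#'
#' Runs [measure_series()] over a collection of recordings — a
#' [generate_sweep()] result, a list of [voltage_series()], or a manifest
#' file path (read via [read_sweep()]) — and returns one row per series.
#' Per-series failures are caught, reported in a warning summary, and leave
#' `NA` rows rather than aborting the run. Results are deterministic given
#' the inputs and options.
#'
#' @param input A `voltage_sweep`, list of `voltage_series`, or manifest
#'   path.
#' @param ... Options passed to [measure_series()] (e.g. `measures`,
#'   `detrend_mode`, `m`, `r`).
#' @param out_dir Optional directory; when given, `measures.csv` and a
#'   `provenance.json` recording the effective options are written there.
#' @return Data frame, one row per series (plus class `measure_table`).
#' @export
run_measure <- function(input, ..., out_dir = NULL) {
  series <- if (inherits(input, "voltage_sweep")) input$series
            else if (is.character(input) && length(input) == 1) read_sweep(input)
            else if (is.list(input)) input
            else stop("input must be a voltage_sweep, list of series, or manifest path")
  if (length(series) == 0) stop("no input series")
  opts <- list(...)
  rows <- vector("list", length(series))
  failures <- character(0)
  for (i in seq_along(series)) {
    rows[[i]] <- tryCatch(measure_series(series[[i]], ...),
                          error = function(e) {
                            failures <<- c(failures, sprintf(
                              "%s: %s", series[[i]]$label,
                              conditionMessage(e)))
                            NULL
                          })
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all series failed:\n",
                     paste(failures, collapse = "\n"))
  if (length(failures))
    warning(length(failures), " series failed:\n",
            paste(failures, collapse = "\n"))
  tab <- do.call(rbind, rows[ok])
  class(tab) <- c("measure_table", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "measures.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(stage = "measure", options = opts,
                              n_series = nrow(tab),
                              n_failed = length(failures)),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tab
}

#' Profile a measure table and localise the critical temperature
#'
#' Aggregates a [run_measure()] table into a temperature profile, fits the
#' Lorentzian resonance on each requested channel, and evaluates the
#' cross-measure proportionality. Channel fit failures are recorded and the
#' remaining channels proceed.
#'
#' @param measures A measure table (data frame with `temperature` and
#'   measure columns).
#' @param channels Channels to fit (default all of `s_s`, `s_a`, `lambda`,
#'   `beta` that are present).
#' @param weights,floor Passed to [localize_tc()].
#' @param proportionality_threshold Passed to [proportionality_check()].
#' @param out_dir Optional output directory for `profile.csv`, `fits.json`
#'   and `report.md`.
#' @return Object of class `sweep_report`: list with `profile`, `fits`
#'   (named list of [lorentz_fit()] objects), `failed` (named character of
#'   failures), `proportionality`.
#' @export
run_profile <- function(measures,
                        channels = c("s_s", "s_a", "lambda", "beta"),
                        weights = "none", floor = 1e-6,
                        proportionality_threshold = 0.7,
                        out_dir = NULL) {
  profile <- build_profile(measures)
  present <- vapply(channels, function(ch)
    paste0(ch, "_mean") %in% names(profile) &&
      any(is.finite(profile[[paste0(ch, "_mean")]])), logical(1))
  channels <- channels[present]
  fits <- list(); failed <- character(0)
  for (ch in channels) {
    f <- tryCatch(localize_tc(profile, channel = ch, weights = weights,
                              floor = floor),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "lorentz_fit")) fits[[ch]] <- f
    else failed[ch] <- f
  }
  prop <- tryCatch(
    proportionality_check(profile, threshold = proportionality_threshold,
                          floor = floor),
    error = function(e) NULL)
  rep <- structure(list(profile = profile, fits = fits, failed = failed,
                        proportionality = prop),
                   class = "sweep_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(profile),
                       file.path(out_dir, "profile.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(fits, function(f) list(
        channel = f$channel,
        coefficients = as.list(f$coefficients),
        stderr = as.list(f$stderr),
        r_squared = f$r_squared, y_error = f$y_error, fwhm = f$fwhm,
        weighting = f$weighting, inversion_floor = f$inversion_floor,
        convention = f$convention)),
      file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
    writeLines(format_report_md(rep), file.path(out_dir, "report.md"))
  }
  rep
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> %d temperatures, %d channel fits\n",
              nrow(x$profile), length(x$fits)))
  for (f in x$fits) print(f)
  if (length(x$failed))
    cat("  failed channels:", paste(names(x$failed), collapse = ", "), "\n")
  if (!is.null(x$proportionality))
    cat(sprintf("  proportionality supported: %s\n",
                if (x$proportionality$supported) "yes" else "no"))
  invisible(x)
}

format_report_md <- function(rep) {
  lines <- c("# Temperature-criticality report", "",
             sprintf("%d temperatures, %d channel fits.",
                     nrow(rep$profile), length(rep$fits)), "",
             "| channel | t_c (degC) | HWHM (degC) | R^2 | y_error |",
             "|---|---|---|---|---|")
  for (f in rep$fits) {
    cf <- f$coefficients
    lines <- c(lines, sprintf("| %s | %.3f +/- %.3f | %.3f | %.3f | %.3f |",
                              f$channel, cf["t_c"], f$stderr["t_c"],
                              cf["half_width"], f$r_squared, f$y_error))
  }
  if (length(rep$failed))
    lines <- c(lines, "", paste("Failed channels:",
                                paste(names(rep$failed), collapse = ", ")))
  if (!is.null(rep$proportionality)) {
    p <- rep$proportionality
    lines <- c(lines, "",
               sprintf("Proportionality (all pairwise r >= %.2f): %s",
                       p$threshold, if (p$supported) "supported" else "not supported"))
  }
  lines
}
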