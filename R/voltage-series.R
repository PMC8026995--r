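#' Construct a voltage time series
#'
#' A `voltage_series` is one uniformly sampled recording of the extracellular
#' ionic-flux electromotive force: a numeric vector of voltages (conventionally
#' in microvolts), a sampling rate in Hz, and optional metadata tying it to a
#' temperature sweep (bath temperature in degrees Celsius and a replicate
#' channel id).
#'
#' @param samples Numeric vector of voltages, length at least 2, no missing
#'   values.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param temperature Bath temperature in degrees Celsius, or `NA` when the
#'   series is not part of a sweep.
#' @param replicate_id Small integer identifying the replicate channel.
#' @param label Free-text label.
#' @return An object of class `voltage_series`.
#' @examples
#' vs <- voltage_series(sin(seq(0, 10, by = 0.25)), sampling_rate = 4)
#' vs
#' @export
voltage_series <- function(samples, sampling_rate, temperature = NA_real_,
                           replicate_id = 1L, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a voltage series needs at least 2 samples")
  if (anyNA(samples)) stop("voltage series may not contain missing values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)")
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         temperature = as.numeric(temperature)[1],
         replicate_id = as.integer(replicate_id)[1],
         label = as.character(label)[1]),
    class = "voltage_series")
}

#' @export
print.voltage_series <- function(x, ...) {
  cat(sprintf("<voltage_series> %d samples @ %.4g Hz", length(x$samples),
              x$sampling_rate))
  if (is.finite(x$temperature))
    cat(sprintf(", T = %.2f degC (replicate %d)", x$temperature,
                x$replicate_id))
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat(sprintf("\n  range [%.4g, %.4g] uV, sd %.4g uV\n",
              min(x$samples), max(x$samples), stats::sd(x$samples)))
  invisible(x)
}

#' @export
length.voltage_series <- function(x) length(x$samples)

as_voltage_series <- function(x, sampling_rate = 1) {
  if (inherits(x, "voltage_series")) x
  else voltage_series(x, sampling_rate = sampling_rate)
}
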