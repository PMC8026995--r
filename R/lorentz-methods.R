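#' @export
print.lorentz_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("<lorentz_fit>")
  if (!is.na(x$channel)) cat(" channel:", x$channel)
  cat("\n")
  cat(sprintf("  t_c = %.4f +/- %.4f degC, HWHM = %.4f +/- %.4f degC\n",
              cf["t_c"], x$stderr["t_c"], cf["half_width"],
              x$stderr["half_width"]))
  cat(sprintf("  amplitude = %.4g, baseline = %.4g, R^2 = %.4f, y_error = %.4f\n",
              cf["amplitude"], cf["baseline"], x$r_squared, x$y_error))
  invisible(x)
}

#' @export
coef.lorentz_fit <- function(object, ...) object$coefficients

#' @export
summary.lorentz_fit <- function(object, ...) {
  cf <- object$coefficients
  tab <- data.frame(estimate = cf, std_error = object$stderr[names(cf)])
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 y_error = object$y_error, fwhm = object$fwhm,
                 channel = object$channel, n = nrow(object$data),
                 convention = object$convention),
            class = "summary.lorentz_fit")
}

#' @export
print.summary.lorentz_fit <- function(x, ...) {
  cat("Lorentzian resonance fit")
  if (!is.na(x$channel)) cat(" (channel ", x$channel, ")", sep = "")
  cat("\n\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nFWHM %.4f degC | R^2 %.4f | y_error %.4f | n = %d\n",
              x$fwhm, x$r_squared, x$y_error, x$n))
  cat(x$convention, "\n")
  invisible(x)
}

#' Evaluate a fitted Lorentzian at new temperatures
#'
#' @param object A [lorentz_fit()] object.
#' @param newdata Optional numeric vector of temperatures (or data frame
#'   with column `x`); defaults to the fitted temperatures.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.lorentz_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x
       else as.numeric(newdata)
  unname(cf["baseline"] + cf["amplitude"] * cf["half_width"]^2 /
           ((x - cf["t_c"])^2 + cf["half_width"]^2))
}

#' @export
residuals.lorentz_fit <- function(object, ...) object$residuals

#' @export
fitted.lorentz_fit <- function(object, ...) object$fitted

#' Plot a Lorentzian critical-temperature fit
#'
#' Data points, the fitted resonance curve on a fine temperature grid, and
#' a dashed marker at the fitted critical temperature.
#'
#' @param x A [lorentz_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lorentz_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$x), max(d$x), length.out = 200)
  args <- list(x = d$x, y = d$y,
               xlab = "Temperature (degC)",
               ylab = if (is.na(x$channel)) "measure" else x$channel,
               main = sprintf("t_c = %.2f degC, HWHM = %.2f degC, R^2 = %.2f",
                              x$coefficients["t_c"],
                              x$coefficients["half_width"], x$r_squared),
               pch = 19)
  do.call(graphics::plot, utils::modifyList(args, list(...)))
  graphics::lines(grid, predict(x, grid), col = "red", lwd = 2)
  graphics::abline(v = x$coefficients["t_c"], lty = 2, col = "grey40")
  invisible(x)
}
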