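#' Fit an external calibration curve
#'
#' Ordinary least-squares line of instrument response on known
#' concentration, as used for external calibration of authentic quinone
#' standards.
#'
#' @param concentration,response Numeric vectors of equal length with at
#'   least two distinct concentration levels.
#' @return An object of class `"externalCalibration"` with the fitted
#'   intercept/slope, R-squared and the calibrated range.
#' @export
externalCalibration <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 2L)
    stop("calibration requires at least two distinct concentration levels")
  fit <- lm(response ~ concentration)
  structure(list(
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    r.squared = suppressWarnings(summary(fit)$r.squared),
    range = range(concentration), fit = fit),
    class = "externalCalibration")
}

#' @export
print.externalCalibration <- function(x, ...) {
  cat(sprintf(
    "External calibration: response = %.4g + %.4g * conc (R^2 = %.4f), range [%g, %g]\n",
    x$intercept, x$slope, x$r.squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Back-calculate concentrations from a calibration model
#'
#' Inverts the fitted line; responses mapping outside the calibrated
#' concentration range are flagged as extrapolated.
#'
#' @param model An [externalCalibration()] fit.
#' @param response Numeric responses to invert.
#' @return data.frame with columns `response`, `concentration`,
#'   `extrapolated`.
#' @export
backCalculate <- function(model, response) {
  stopifnot(inherits(model, "externalCalibration"))
  if (model$slope == 0) stop("calibration slope is zero; cannot invert")
  conc <- (response - model$intercept) / model$slope
  data.frame(response = response, concentration = conc,
             extrapolated = conc < model$range[1] | conc > model$range[2])
}
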