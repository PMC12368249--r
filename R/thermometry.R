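#' Arrhenius calibration of pipette-resistance thermometry
#'
#' The ionic conductivity of the pipette electrolyte follows an Arrhenius
#' law, so `ln(R)` is linear in `1/T` with slope `E_a / R_gas`. A
#' least-squares line fitted to calibration pairs yields the activation
#' energy `E_a`; the reference resistance `R_0` is the fitted resistance at
#' the reference temperature `T_0`.
#'
#' @param pairs data frame or matrix with columns `resistance` (Ohm) and
#'   `temperature` (K); at least 3 pairs spanning >= 5 K.
#' @param T0 reference temperature in K (defaults to the lowest calibration
#'   temperature, i.e. room temperature).
#' @return an object of class `thermometry_calibration`: `E_a` (J/mol),
#'   `R_gas` (8.314 J/(mol K)), `T_0` (K), `R_0` (Ohm), `fit` (slope,
#'   intercept, r_squared).
#' @export
fit_arrhenius <- function(pairs, T0 = NULL) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("resistance", "temperature")
  if (any(pairs$resistance <= 0) || any(pairs$temperature <= 0))
    stop_param("resistances and temperatures must be positive")
  if (nrow(pairs) < 3L) stop_param("need at least 3 calibration pairs")
  if (diff(range(pairs$temperature)) < 5)
    stop_param("calibration must span at least 5 K")
  x <- 1 / pairs$temperature
  y <- log(pairs$resistance)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  R_gas <- 8.314
  if (is.null(T0)) T0 <- min(pairs$temperature)
  structure(
    list(E_a = slope * R_gas, R_gas = R_gas, T_0 = T0,
         R_0 = exp(intercept + slope / T0),
         fit = list(slope = slope, intercept = intercept,
                    # suppress the "essentially perfect fit" warning that
                    # noiseless calibration tables otherwise raise
                    r_squared = suppressWarnings(summary(fit)$r.squared))),
    class = "thermometry_calibration")
}

#' @export
print.thermometry_calibration <- function(x, ...) {
  cat(sprintf("<thermometry_calibration> E_a = %.3f kJ/mol, R_0 = %.3f MOhm at T_0 = %.2f K (R^2 = %.4f)\n",
              x$E_a / 1000, x$R_0 / 1e6, x$T_0, x$fit$r_squared))
  invisible(x)
}

#' Convert pipette resistance to temperature
#'
#' Evaluates `T_i = [1 / T_0 - R_gas / E_a * ln(R_0 / R_i)]^-1`: warming
#' increases electrolyte conductivity, so resistances below `R_0` map to
#' temperatures above `T_0`.
#'
#' @param R_i measured pipette resistance in Ohm (> 0; vectorised).
#' @param cal a [fit_arrhenius()] calibration.
#' @return temperature(s) in K.
#' @export
resistance_to_temperature <- function(R_i, cal) {
  if (any(R_i <= 0)) stop_param("`R_i` must be positive")
  inv <- 1 / cal$T_0 - cal$R_gas / cal$E_a * log(cal$R_0 / R_i)
  if (any(inv <= 0)) stop_param("resistance outside the calibrated domain")
  1 / inv
}

#' Invert the thermometry equation: temperature to resistance
#'
#' @param T_i temperature(s) in K.
#' @param cal a [fit_arrhenius()] calibration.
#' @return resistance(s) in Ohm.
#' @export
temperature_to_resistance <- function(T_i, cal) {
  if (any(T_i <= 0)) stop_param("`T_i` must be positive")
  cal$R_0 * exp(cal$E_a / cal$R_gas * (1 / T_i - 1 / cal$T_0))
}
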