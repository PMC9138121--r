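# Domain objects: validated parameter containers used across the package.
# Frames (raw digital numbers, temperatures, label masks) are plain R
# matrices in image orientation: mat[row, col] == pixel (y, x).

ir_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "irproc_error", "error", "condition")))
}

ir_warn <- function(msg, class = "irproc_warning") {
  warning(warningCondition(msg, class = c(class, "warning", "condition")))
}

.check_num <- function(x, name, class = "ir_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ir_stop(sprintf("'%s' must be a single finite number", name), class)
  as.numeric(x)
}

#' Sensor calibration constants
#'
#' Per-camera constants of the Planck-type sensor calibration model
#' \eqn{S = G / (R (e^{B/T} - F)) + O}, which links the digital number
#' (DN) produced by the sensor to the absolute temperature \eqn{T} (K) of
#' a black body filling its field of view. In camera metadata these are
#' stored as the "Planck" tags (R1 = G, O, B, F, R2 = R).
#'
#' @param G Sensor gain (DN per unit radiance). Must be > 0.
#' @param O Sensor offset (DN). Typically a large negative number.
#' @param B Exponential calibration constant (kelvin). Must be > 0.
#' @param R Radiance scaling constant. Must be > 0.
#' @param F Calibration constant generalizing the literal 1 in the
#'   Planck denominator; cameras usually store 1. Must be > 0.
#' @return An object of class `calibration_constants`.
#' @examples
#' calibration_constants(G = 21106.77, O = -7261, B = 1501, R = 0.012545)
#' @export
calibration_constants <- function(G, O, B, R, F = 1) {
  G <- .check_num(G, "G"); O <- .check_num(O, "O"); B <- .check_num(B, "B")
  R <- .check_num(R, "R"); F <- .check_num(F, "F")
  if (G <= 0) ir_stop("sensor gain G must be > 0", "ir_parameter_error")
  if (R <= 0) ir_stop("calibration constant R must be > 0", "ir_parameter_error")
  if (B <= 0) ir_stop("calibration constant B must be > 0", "ir_parameter_error")
  if (F <= 0) ir_stop("calibration constant F must be > 0", "ir_parameter_error")
  structure(list(G = G, O = O, B = B, R = R, F = F),
            class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, ...) {
  cat("Sensor calibration constants:\n")
  cat(sprintf("  G = %g  O = %g  B = %g K  R = %g  F = %g\n",
              x$G, x$O, x$B, x$R, x$F))
  invisible(x)
}

#' Atmospheric transmissivity model coefficients
#'
#' Coefficients of the two-exponential attenuation model
#' \eqn{\tau = X e^{-\sqrt d (\alpha_1 + \beta_1 \sqrt H)} +
#' (1-X) e^{-\sqrt d (\alpha_2 + \beta_2 \sqrt H)}}, where \eqn{d} is the
#' object distance (m) and \eqn{H} the air water content. Cameras store
#' these as the "Atmospheric Trans" tags.
#'
#' @param alpha1,alpha2 Attenuation coefficients of the two exponential terms.
#' @param beta1,beta2 Water-content sensitivities of the two terms.
#' @param X Mixing weight between the two terms; sanity-bounded to [0, 2].
#' @return An object of class `atmosphere_model`.
#' @export
atmosphere_model <- function(alpha1, alpha2, beta1, beta2, X) {
  alpha1 <- .check_num(alpha1, "alpha1"); alpha2 <- .check_num(alpha2, "alpha2")
  beta1 <- .check_num(beta1, "beta1"); beta2 <- .check_num(beta2, "beta2")
  X <- .check_num(X, "X")
  if (X < 0 || X > 2)
    ir_stop("atmospheric mixing weight X outside the sane range [0, 2]",
            "ir_parameter_error")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, X = X),
            class = "atmosphere_model")
}

#' @export
print.atmosphere_model <- function(x, ...) {
  cat("Atmospheric transmissivity model:\n")
  cat(sprintf("  alpha1 = %g  beta1 = %g\n  alpha2 = %g  beta2 = %g\n  X = %g\n",
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$X))
  invisible(x)
}

#' User-set acquisition parameters
#'
#' Per-image parameters describing the measurement conditions: surface
#' emissivity of the target, air temperature, relative humidity, apparent
#' reflected temperature (reading from a near-perfect reflector such as
#' crumpled aluminium foil, quantifying radiation reflected off the
#' target) and object-to-camera distance.
#'
#' Relative humidity is held internally as a fraction in [0, 1]. Values
#' given in percent (> 1, as stored by cameras under a `_perc` tag) are
#' divided by 100 on ingest.
#'
#' @param emissivity Target surface emissivity, in (0, 1].
#' @param air_temp_C Air temperature (degrees C).
#' @param rel_humidity Relative humidity as a fraction in [0, 1], or in
#'   percent if > 1.
#' @param app_refl_temp_C Apparent reflected temperature (degrees C).
#' @param distance_m Object distance from the camera (metres), >= 0.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params(0.95, air_temp_C = 20, rel_humidity = 0.5,
#'                    app_refl_temp_C = 20, distance_m = 1)
#' @export
acquisition_params <- function(emissivity, air_temp_C, rel_humidity,
                               app_refl_temp_C, distance_m) {
  emissivity <- .check_num(emissivity, "emissivity")
  air_temp_C <- .check_num(air_temp_C, "air_temp_C")
  rel_humidity <- .check_num(rel_humidity, "rel_humidity")
  app_refl_temp_C <- .check_num(app_refl_temp_C, "app_refl_temp_C")
  distance_m <- .check_num(distance_m, "distance_m")
  if (rel_humidity > 1 && rel_humidity <= 100) rel_humidity <- rel_humidity / 100
  if (emissivity <= 0 || emissivity > 1)
    ir_stop("emissivity must lie in (0, 1]", "ir_parameter_error")
  if (rel_humidity < 0 || rel_humidity > 1)
    ir_stop("relative humidity must lie in [0, 1] (or [0, 100] percent)",
            "ir_parameter_error")
  if (distance_m < 0)
    ir_stop("object distance must be >= 0", "ir_parameter_error")
  if (air_temp_C <= -273.15 || app_refl_temp_C <= -273.15)
    ir_stop("temperatures must be above absolute zero (-273.15 C)",
            "ir_invalid_temperature")
  structure(list(emissivity = emissivity, air_temp_C = air_temp_C,
                 rel_humidity = rel_humidity,
                 app_refl_temp_C = app_refl_temp_C,
                 distance_m = distance_m),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Acquisition parameters:\n")
  cat(sprintf(
    "  emissivity = %g  air temp = %g C  RH = %g  refl temp = %g C  distance = %g m\n",
    x$emissivity, x$air_temp_C, x$rel_humidity, x$app_refl_temp_C, x$distance_m))
  invisible(x)
}

.check_raw_frame <- function(dn) {
  if (!is.matrix(dn) || !is.numeric(dn))
    ir_stop("raw frame must be a numeric matrix of digital numbers",
            "ir_format_error")
  if (nrow(dn) < 1L || ncol(dn) < 1L)
    ir_stop("raw frame has zero extent", "ir_format_error")
  if (any(dn < 0 | dn > 65535, na.rm = TRUE))
    ir_stop("digital numbers outside the 16-bit range [0, 65535]",
            "ir_format_error")
  dn
}

.check_same_dim <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    ir_stop(sprintf("dimension mismatch: %s", what), "ir_dimension_error")
  invisible(TRUE)
}
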