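# Radiometric core: sensor calibration model, three-source signal
# decomposition, atmospheric transmissivity, and the inversion from raw
# digital numbers to object temperature.
#
# Signal model. The sensor output S (in digital numbers, DN) measured for
# a scene is decomposed into three sources:
#
#     S = tau * S_obj + tau * S_refl + S_atm
#
# where S_obj is the equivalent signal emitted by the object, S_refl the
# signal reflected off the object's surface from its surroundings (both
# attenuated by atmospheric transmissivity tau), and S_atm the signal
# emitted by the air column itself. Each component follows the
# Planck-type calibration law
#
#     S_x = G * w / (R * (exp(B / T) - F)) + O
#
# with weight w = emissivity for the object, (1 - tau) for the
# atmosphere, and (1 - emissivity) for the reflected term (evaluated at
# the apparent reflected temperature). Inversion solves the
# decomposition for S_obj and then the calibration law for T.

#' Convert between Celsius and kelvin
#'
#' @param t_C Temperature in degrees Celsius. Must exceed absolute zero.
#' @return Temperature in kelvin.
#' @export
celsius_to_kelvin <- function(t_C) {
  if (!is.numeric(t_C) || any(!is.finite(t_C)))
    ir_stop("temperature must be finite", "ir_invalid_temperature")
  if (any(t_C <= -273.15))
    ir_stop("temperature at or below absolute zero (-273.15 C)",
            "ir_invalid_temperature")
  t_C + 273.15
}

#' @rdname celsius_to_kelvin
#' @param t_K Temperature in kelvin, > 0.
#' @export
kelvin_to_celsius <- function(t_K) {
  if (!is.numeric(t_K) || any(!is.finite(t_K)) || any(t_K <= 0))
    ir_stop("kelvin temperature must be finite and > 0",
            "ir_invalid_temperature")
  t_K - 273.15
}

#' Air water content from temperature and relative humidity
#'
#' Empirical water-content model used by the atmospheric transmissivity
#' correction: `H = RH * exp(1.5587 + 6.939e-2 t - 2.7816e-4 t^2 +
#' 6.8455e-7 t^3)` with air temperature `t` in degrees C.
#'
#' @param air_temp_C Air temperature in degrees C (finite scalar or vector).
#' @param rel_humidity Relative humidity as a fraction in [0, 1].
#' @return Air water content H (model units).
#' @examples
#' air_water_content(20, 0.5)  # about 8.56
#' @export
air_water_content <- function(air_temp_C, rel_humidity) {
  if (!is.numeric(rel_humidity) || any(rel_humidity < 0 | rel_humidity > 1))
    ir_stop("relative humidity must lie in [0, 1]", "ir_parameter_error")
  if (!is.numeric(air_temp_C) || any(!is.finite(air_temp_C)))
    ir_stop("air temperature must be finite", "ir_parameter_error")
  t <- air_temp_C
  rel_humidity * exp(1.5587 + 6.939e-2 * t - 2.7816e-4 * t^2 + 6.8455e-7 * t^3)
}

#' Atmospheric transmissivity over an object distance
#'
#' Two-term exponential attenuation model:
#' `tau = X exp(-sqrt(d) (alpha1 + beta1 sqrt(H))) +
#'  (1 - X) exp(-sqrt(d) (alpha2 + beta2 sqrt(H)))`.
#' At `d = 0` the transmissivity is exactly 1. The result is clamped to
#' `[1e-6, 1]` to protect the downstream division for absurd distances;
#' a warning is raised when clamping actually occurs.
#'
#' @param distance_m Object distance in metres, >= 0.
#' @param H Air water content, >= 0 (see [air_water_content()]).
#' @param atm An [atmosphere_model()].
#' @return Atmospheric transmissivity tau in (0, 1].
#' @export
atmospheric_transmissivity <- function(distance_m, H, atm) {
  stopifnot(inherits(atm, "atmosphere_model"))
  if (!is.numeric(distance_m) || any(distance_m < 0))
    ir_stop("object distance must be >= 0", "ir_parameter_error")
  if (!is.numeric(H) || any(H < 0))
    ir_stop("air water content must be >= 0", "ir_parameter_error")
  sd_ <- sqrt(distance_m)
  sh <- sqrt(H)
  tau <- atm$X * exp(-sd_ * (atm$alpha1 + atm$beta1 * sh)) +
    (1 - atm$X) * exp(-sd_ * (atm$alpha2 + atm$beta2 * sh))
  if (any(tau < 1e-6 | tau > 1)) {
    ir_warn("atmospheric transmissivity clamped to [1e-6, 1]",
            "ir_tau_clamped")
    tau <- pmin(pmax(tau, 1e-6), 1)
  }
  tau
}

#' Component signal of the three-source decomposition
#'
#' Equivalent digital signal emitted by a source at absolute temperature
#' `T_K` weighted by `weight`: `G * weight / (R * (exp(B/T) - F)) + O`
#' (offset included by default). With `weight = emissivity` this is the
#' object signal; with `weight = 1 - tau` at air temperature, the
#' atmosphere signal; with `weight = 1 - emissivity` at the apparent
#' reflected temperature, the reflected signal.
#'
#' @param T_K Source absolute temperature (kelvin), > 0.
#' @param weight Emission weight in [0, 1].
#' @param cal [calibration_constants()].
#' @param include_offset Include the sensor offset O in the returned
#'   signal (the documented convention). Set `FALSE` only to reconcile
#'   against third-party formulations that keep components offset-free.
#' @return Signal in DN-valued real numbers (not quantized).
#' @export
component_signal <- function(T_K, weight, cal, include_offset = TRUE) {
  stopifnot(inherits(cal, "calibration_constants"))
  if (!is.numeric(T_K) || any(T_K <= 0))
    ir_stop("absolute temperature must be > 0 K", "ir_invalid_temperature")
  if (!is.numeric(weight) || any(weight < 0 | weight > 1))
    ir_stop("emission weight must lie in [0, 1]", "ir_parameter_error")
  denom <- exp(cal$B / T_K) - cal$F
  if (any(denom <= 0))
    ir_stop("exp(B/T) <= F: outside the calibration model's domain",
            "ir_numeric_domain_error")
  cal$G * weight / (cal$R * denom) + if (include_offset) cal$O else 0
}

#' Object signal from the measured total signal
#'
#' Solves the three-source decomposition for the object term:
#' `S_obj = S / tau - S_refl - S_atm / tau`.
#'
#' @param S Measured total signal (DN).
#' @param tau Atmospheric transmissivity in (0, 1].
#' @param S_refl Equivalent reflected signal (DN).
#' @param S_atm Equivalent atmosphere signal (DN).
#' @return Object signal S_obj (DN-valued real).
#' @export
object_signal <- function(S, tau, S_refl, S_atm) {
  if (!is.numeric(tau) || any(tau <= 0 | tau > 1))
    ir_stop("transmissivity must lie in (0, 1]", "ir_parameter_error")
  S / tau - S_refl - S_atm / tau
}

#' Object temperature from the object signal
#'
#' Inverts the Planck-type calibration law:
#' `T = B / log(G * emissivity / (R * (S_obj - O)) + F)` with the natural
#' logarithm. This is the exact inverse of [component_signal()] at the
#' same emissivity. No floor or clamp is applied to the result: signals
#' corresponding to very cold surfaces invert to their true temperature
#' (there is deliberately no artificial lower bound such as the -40 C
#' floor some vendor software applies).
#'
#' @param S_obj Object signal (DN-valued real). Must exceed the sensor
#'   offset O; at or below it the logarithm's argument leaves the model's
#'   domain and the pixel is undefined.
#' @param emissivity Target emissivity in (0, 1].
#' @param cal [calibration_constants()].
#' @return Object temperature in kelvin.
#' @export
object_temperature <- function(S_obj, emissivity, cal) {
  stopifnot(inherits(cal, "calibration_constants"))
  if (!is.numeric(emissivity) || any(emissivity <= 0 | emissivity > 1))
    ir_stop("emissivity must lie in (0, 1]", "ir_parameter_error")
  if (any(S_obj <= cal$O))
    ir_stop("object signal at or below the sensor offset: temperature undefined",
            "ir_signal_domain_error")
  .object_temperature_raw(S_obj, emissivity, cal)
}

# Vectorized inversion mapping out-of-domain signals to NaN instead of
# erroring; used by frame operations.
.object_temperature_raw <- function(S_obj, emissivity, cal) {
  arg <- cal$G * emissivity / (cal$R * (S_obj - cal$O)) + cal$F
  bad <- S_obj <= cal$O | arg <= 0
  arg[bad] <- NA_real_
  T_K <- cal$B / log(arg)
  T_K[bad] <- NaN
  T_K
}

#' Per-image derived atmospheric quantities
#'
#' Computes, once per image, the quantities derived from the acquisition
#' parameters: air water content H, atmospheric transmissivity tau, the
#' equivalent atmosphere signal (emission weight `1 - tau` at air
#' temperature) and the equivalent reflected signal (weight
#' `1 - emissivity` at the apparent reflected temperature).
#'
#' @param params [acquisition_params()].
#' @param cal [calibration_constants()].
#' @param atm [atmosphere_model()].
#' @return A list with elements `H`, `tau`, `S_atm`, `S_refl`.
#' @export
derive_atmosphere <- function(params, cal, atm) {
  stopifnot(inherits(params, "acquisition_params"))
  H <- air_water_content(params$air_temp_C, params$rel_humidity)
  tau <- atmospheric_transmissivity(params$distance_m, H, atm)
  S_atm <- component_signal(celsius_to_kelvin(params$air_temp_C),
                            1 - tau, cal)
  S_refl <- component_signal(celsius_to_kelvin(params$app_refl_temp_C),
                             1 - params$emissivity, cal)
  list(H = H, tau = tau, S_atm = S_atm, S_refl = S_refl)
}

#' Convert a raw frame to a temperature frame
#'
#' Applies the full inversion chain to every pixel of a raw digital
#' number frame: the derived atmospheric quantities are computed once per
#' frame, then each pixel's object signal is recovered from the
#' three-source decomposition and inverted through the calibration law.
#' Pixels whose object signal falls outside the model's domain (at or
#' below the sensor offset) become `NaN`; they never abort the frame.
#'
#' @param raw Numeric matrix of digital numbers in [0, 65535] (integer
#'   DN from a camera, or unquantized DN-valued reals from the synthetic
#'   forward model).
#' @param params [acquisition_params()].
#' @param cal [calibration_constants()].
#' @param atm [atmosphere_model()].
#' @return Numeric matrix of object temperatures in degrees C, same
#'   dimensions as `raw`, with `NaN` marking undefined pixels. The number
#'   of undefined pixels is attached as attribute `undefined_pixels`.
#' @export
frame_to_temperature <- function(raw, params, cal, atm) {
  .check_raw_frame(raw)
  der <- derive_atmosphere(params, cal, atm)
  S_obj <- object_signal(raw, der$tau, der$S_refl, der$S_atm)
  T_K <- .object_temperature_raw(S_obj, params$emissivity, cal)
  temp_C <- T_K - 273.15
  dim(temp_C) <- dim(raw)
  n_bad <- sum(is.nan(temp_C))
  if (n_bad > 0L)
    message(sprintf("frame_to_temperature: %d pixel(s) undefined (signal outside model domain)",
                    n_bad))
  attr(temp_C, "undefined_pixels") <- n_bad
  temp_C
}
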