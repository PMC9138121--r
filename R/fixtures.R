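# Synthetic scene generator: the forward radiometric model. Produces
# known temperature fields, composes the three-source signal exactly as
# the inversion expects, and packages the result as sidecar fixtures
# readable by the I/O layer as if they came from a camera.

#' Default synthetic calibration constants and atmosphere model
#'
#' Representative constants for a long-wave microbolometer camera, used
#' as fixture defaults throughout the package: G = 21106.77, O = 2000,
#' B = 1501 K, R = 0.012545, F = 1, and atmosphere alpha1 = 0.006569,
#' alpha2 = 0.01262, beta1 = -0.002276, beta2 = -0.00667, X = 1.9.
#' They are synthetic defaults with realistic magnitudes, not
#' measurements of any particular camera. The synthetic camera's offset
#' is positive: in the three-source composition the sensor offset enters
#' each component signal, so the total carries it (2 tau + 1) times, and
#' a positive offset keeps the composed signal inside the 16-bit
#' converter range over scene temperatures from -70 to +60 degrees C.
#'
#' @return [calibration_constants()] / [atmosphere_model()] objects.
#' @export
default_calibration <- function() {
  calibration_constants(G = 21106.77, O = 2000, B = 1501, R = 0.012545, F = 1)
}

#' @rdname default_calibration
#' @export
default_atmosphere <- function() {
  atmosphere_model(alpha1 = 0.006569, alpha2 = 0.01262,
                   beta1 = -0.002276, beta2 = -0.00667, X = 1.9)
}

#' Describe an object to paint into a synthetic scene
#'
#' @param shape `"rectangle"` or `"disk"`.
#' @param x,y Centre of the object in pixel coordinates (column, row).
#' @param width,height Rectangle extent in pixels (ignored for disks).
#' @param radius Disk radius in pixels (ignored for rectangles).
#' @param temp_C Object surface temperature (degrees C).
#' @param emissivity Object emissivity; `NULL` inherits the scene's
#'   acquisition emissivity.
#' @return A `scene_object` list.
#' @export
scene_object <- function(shape = c("rectangle", "disk"), x, y,
                         width = NULL, height = NULL, radius = NULL,
                         temp_C, emissivity = NULL) {
  shape <- match.arg(shape)
  if (temp_C <= -273.15)
    ir_stop("object temperature at or below absolute zero",
            "ir_invalid_temperature")
  structure(list(shape = shape, x = x, y = y, width = width,
                 height = height, radius = radius, temp_C = temp_C,
                 emissivity = emissivity),
            class = "scene_object")
}

#' Specify a synthetic thermal scene
#'
#' A scene is a uniform background at a known temperature with a list of
#' rectangular or disk-shaped objects painted over it (later objects win
#' on overlap), imaged under given acquisition parameters with given
#' calibration constants and atmosphere model. Gaussian sensor noise (in
#' DN) and 16-bit quantization are optional and seeded.
#'
#' @param width,height Scene extent in pixels.
#' @param background_C Background temperature (degrees C).
#' @param objects List of [scene_object()]s.
#' @param params [acquisition_params()]; the default images a typical
#'   leaf-phenotyping setup (emissivity 0.95, 20 C air, 50% RH, 1 m).
#' @param cal [calibration_constants()].
#' @param atm [atmosphere_model()].
#' @param noise_sd Gaussian noise standard deviation added to the DN
#'   signal, >= 0.
#' @param quantize Round the signal to unsigned 16-bit integers (as a
#'   real sensor does). `FALSE` keeps unquantized DN-valued reals.
#' @param seed Integer seed for the noise generator.
#' @param camera_model Camera model string stamped into the metadata.
#' @param image_type `"PNG"` or `"TIFF"`: payload container recorded in
#'   the metadata (drives the byte-order rule on readback).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width, height, background_C = 20,
                       objects = list(),
                       params = acquisition_params(0.95, 20, 0.5, 20, 1),
                       cal = default_calibration(),
                       atm = default_atmosphere(),
                       noise_sd = 0, quantize = TRUE, seed = 1L,
                       camera_model = "SYNTH-T1", image_type = "PNG") {
  stopifnot(width >= 1, height >= 1, inherits(params, "acquisition_params"),
            inherits(cal, "calibration_constants"),
            inherits(atm, "atmosphere_model"))
  if (background_C <= -273.15)
    ir_stop("background temperature at or below absolute zero",
            "ir_invalid_temperature")
  if (noise_sd < 0) ir_stop("noise sd must be >= 0", "ir_parameter_error")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_C = background_C, objects = objects,
                 params = params, cal = cal, atm = atm,
                 noise_sd = noise_sd, quantize = isTRUE(quantize),
                 seed = as.integer(seed), camera_model = camera_model,
                 image_type = toupper(image_type)),
            class = "scene_spec")
}

#' Render the true temperature and emissivity fields of a scene
#'
#' Paints objects over the background in list order (painter's rule:
#' later objects overwrite earlier ones). Deterministic given the spec.
#'
#' @param spec A [scene_spec()].
#' @return List with `truth` (matrix, degrees C) and `emissivity`
#'   (matrix) of dimensions `height` x `width`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  truth <- matrix(spec$background_C, spec$height, spec$width)
  emis <- matrix(spec$params$emissivity, spec$height, spec$width)
  xs <- matrix(rep(seq_len(spec$width), each = spec$height),
               spec$height, spec$width)
  ys <- matrix(rep(seq_len(spec$height), spec$width),
               spec$height, spec$width)
  for (ob in spec$objects) {
    sel <- if (ob$shape == "rectangle") {
      if (is.null(ob$width) || is.null(ob$height))
        ir_stop("rectangle object needs width and height", "ir_parameter_error")
      abs(xs - ob$x) <= ob$width / 2 & abs(ys - ob$y) <= ob$height / 2
    } else {
      if (is.null(ob$radius))
        ir_stop("disk object needs a radius", "ir_parameter_error")
      (xs - ob$x)^2 + (ys - ob$y)^2 <= ob$radius^2
    }
    if (!any(sel))
      ir_stop("scene object lies entirely outside the canvas",
              "ir_parameter_error")
    truth[sel] <- ob$temp_C
    e <- if (is.null(ob$emissivity)) spec$params$emissivity else ob$emissivity
    emis[sel] <- e
  }
  list(truth = truth, emissivity = emis)
}

#' Forward radiometric model: temperature field to raw signal
#'
#' Composes the measured signal per pixel as
#' `S = tau * S_obj + tau * S_refl + S_atm`, with the object signal from
#' the pixel's true temperature and emissivity and the reflected and
#' atmosphere signals from the scene's acquisition parameters — exactly
#' the forward counterpart of the inversion in
#' [frame_to_temperature()]. Optionally adds seeded Gaussian DN noise
#' and rounds to unsigned 16 bits (values clipped to [0, 65535] with a
#' warning reporting the clip count).
#'
#' @param truth Matrix of true temperatures (degrees C).
#' @param emissivity Matrix of per-pixel emissivities (same dimensions).
#' @param spec The [scene_spec()] supplying parameters, noise and
#'   quantization settings.
#' @return Matrix of digital numbers (integers if `spec$quantize`,
#'   DN-valued reals otherwise).
#' @export
forward_signal <- function(truth, emissivity, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .check_same_dim(truth, emissivity, "truth vs emissivity map")
  der <- derive_atmosphere(spec$params, spec$cal, spec$atm)
  S_obj <- component_signal(truth + 273.15, emissivity, spec$cal)
  S <- der$tau * S_obj + der$tau * der$S_refl + der$S_atm
  dim(S) <- dim(truth)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    S <- S + matrix(stats::rnorm(length(S), 0, spec$noise_sd),
                    nrow(S), ncol(S))
  }
  n_clip <- sum(S < 0 | S > 65535)
  if (n_clip > 0L)
    ir_warn(sprintf("forward signal clipped at the 16-bit range for %d pixel(s)",
                    n_clip), "ir_signal_clipped")
  if (spec$quantize) {
    S <- round(S)
    S <- pmin(pmax(S, 0), 65535)
    dim(S) <- dim(truth)
  } else if (n_clip > 0L) {
    S <- pmin(pmax(S, 0), 65535)
    dim(S) <- dim(truth)
  }
  S
}

#' Package a raw frame as a sidecar fixture
#'
#' Writes a payload image plus a one-row parameter CSV with the same
#' base name, readable by [extract_metadata()] and
#' [extract_raw_frame()] as if produced by a camera. Quantized frames
#' are stored as 16-bit PNG with the byte order implied by the scene's
#' `image_type` and camera model (so the reader's swap path is
#' exercised); unquantized frames are stored as 32-bit float TIFF
#' ("sidecar float mode", exact to float precision).
#'
#' @param raw Matrix of digital numbers from [forward_signal()].
#' @param spec The [scene_spec()].
#' @param dir Output directory (created if needed).
#' @param basename File base name (without extension).
#' @param exceptions Byte-order exception list used when encoding.
#' @return Named list with `payload` and `params` file paths.
#' @export
package_fixture <- function(raw, spec, dir, basename = "fixture",
                            exceptions = byte_order_exceptions()) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  quantized <- all(raw == round(raw))
  if (quantized) {
    payload <- file.path(dir, paste0(basename, ".png"))
    order <- resolve_byte_order(spec$image_type, spec$camera_model, exceptions)
    stored <- if (order == "little") swap16(raw) else raw
    write_png16(stored, payload)
  } else {
    payload <- file.path(dir, paste0(basename, ".tif"))
    write_tiff_float(raw, payload)
  }
  meta <- structure(list(camera_model = spec$camera_model,
                         raw_image_type = spec$image_type,
                         cal = spec$cal, atm = spec$atm, user = spec$params),
                    class = "image_metadata")
  rec <- .record_from_metadata(meta, basename(payload))
  params_path <- file.path(dir, paste0(basename, ".csv"))
  write_parameter_table(rec, params_path)
  list(payload = payload, params = params_path)
}

#' Generate and package a whole folder of synthetic fixtures
#'
#' Convenience wrapper: for each scene spec, renders the truth field,
#' runs the forward model and writes a sidecar fixture pair into `dir`.
#'
#' @param specs A single [scene_spec()] or list of them.
#' @param dir Output directory.
#' @param basenames File base names; defaults to `img001`, `img002`, ...
#' @return Invisible list of per-fixture `package_fixture()` results,
#'   with each scene's truth field attached as attribute `truth`.
#' @export
simulate_folder <- function(specs, dir, basenames = NULL) {
  if (inherits(specs, "scene_spec")) specs <- list(specs)
  if (is.null(basenames))
    basenames <- sprintf("img%03d", seq_along(specs))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sc <- generate_scene(specs[[i]])
    raw <- forward_signal(sc$truth, sc$emissivity, specs[[i]])
    out[[i]] <- package_fixture(raw, specs[[i]], dir, basenames[i])
    attr(out[[i]], "truth") <- sc$truth
  }
  invisible(out)
}

#' Read a scene specification from JSON
#'
#' The JSON schema mirrors [scene_spec()]: top-level fields `width`,
#' `height`, `background_C`, `noise_sd`, `quantize`, `seed`,
#' `camera_model`, `image_type`, an `objects` array of
#' `{shape, x, y, width, height, radius, temp_C, emissivity}` entries,
#' and optional `params` (`emissivity`, `air_temp_C`, `rel_humidity`,
#' `app_refl_temp_C`, `distance_m`), `cal` (`G`, `O`, `B`, `R`, `F`) and
#' `atm` (`alpha1`, `alpha2`, `beta1`, `beta2`, `X`) objects; omitted
#' blocks fall back to the synthetic defaults.
#'
#' @param path JSON file path.
#' @return A [scene_spec()].
#' @export
read_scene_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  params <- if (!is.null(js$params))
    do.call(acquisition_params, js$params)
  else acquisition_params(0.95, 20, 0.5, 20, 1)
  cal <- if (!is.null(js$cal)) do.call(calibration_constants, js$cal)
  else default_calibration()
  atm <- if (!is.null(js$atm)) do.call(atmosphere_model, js$atm)
  else default_atmosphere()
  objects <- lapply(js$objects, function(o) do.call(scene_object, o))
  scene_spec(width = js$width, height = js$height,
             background_C = js$background_C %||% 20,
             objects = objects, params = params, cal = cal, atm = atm,
             noise_sd = js$noise_sd %||% 0,
             quantize = js$quantize %||% TRUE,
             seed = js$seed %||% 1L,
             camera_model = js$camera_model %||% "SYNTH-T1",
             image_type = js$image_type %||% "PNG")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
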