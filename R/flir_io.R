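# Reading radiometric images (metadata + embedded 16-bit payload) and
# the package's CSV formats.
#
# Two input representations are supported:
#   * radiometric JPEG straight from a camera, read through the external
#     `exiftool` utility (subprocess contract; exiftool must be on PATH);
#   * "sidecar" pairs — a 16-bit PNG (or float TIFF) payload plus a
#     one-row parameter CSV with the same base name — as written by the
#     synthetic fixture generator. Sidecars are parsed in pure R.

# Parameter-record schema: fixed column set and order. One row per image.
.param_columns <- c("filename", "imageType", "cameraModel",
                    "sensorG", "sensorO", "sensorB", "sensorF", "sensorR",
                    "atmAlpha1", "atmAlpha2", "atmBeta1", "atmBeta2", "atmX",
                    "appReflTemp_C", "airTemp_C", "objEmissivity",
                    "airRelHumidity_perc", "objDistance_m")
.param_numeric <- setdiff(.param_columns, c("filename", "imageType", "cameraModel"))

# EXIF tag names (exiftool, spaces stripped) -> record fields
.exif_tag_map <- c(
  RawThermalImageType = "imageType",
  CameraModel = "cameraModel",
  PlanckR1 = "sensorG",
  PlanckO = "sensorO",
  PlanckB = "sensorB",
  PlanckF = "sensorF",
  PlanckR2 = "sensorR",
  AtmosphericTransAlpha1 = "atmAlpha1",
  AtmosphericTransAlpha2 = "atmAlpha2",
  AtmosphericTransBeta1 = "atmBeta1",
  AtmosphericTransBeta2 = "atmBeta2",
  AtmosphericTransX = "atmX",
  ReflectedApparentTemperature = "appReflTemp_C",
  AtmosphericTemperature = "airTemp_C",
  Emissivity = "objEmissivity",
  RelativeHumidity = "airRelHumidity_perc",
  ObjectDistance = "objDistance_m")

#' Camera models that invert the byte-order rule
#'
#' The byte order of the embedded 16-bit payload is normally determined
#' by the payload container (PNG or TIFF), but a few camera models are
#' known to violate the rule. The exception list ships as a plain-text
#' config file (one model name per line, `#` comments) that users can
#' edit; the default file is seeded with the synthetic fixture models
#' used by this package's own tests and must be extended with real
#' offending models as they are identified.
#'
#' @param path Optional path to an exceptions file; defaults to the
#'   config bundled with the package.
#' @return Character vector of camera model names.
#' @export
byte_order_exceptions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "byte_order_exceptions.txt",
                        package = "irproc")
  if (!nzchar(path) || !file.exists(path)) return(character(0))
  ln <- trimws(readLines(path, warn = FALSE))
  ln[nzchar(ln) & !startsWith(ln, "#")]
}

#' Resolve the byte order of an embedded raw payload
#'
#' PNG payloads carry their 16-bit samples byte-swapped relative to the
#' container's declared order (effectively little-endian), TIFF payloads
#' do not (big-endian under the same convention). Camera models on the
#' exception list invert this mapping.
#'
#' @param raw_image_type `"PNG"` or `"TIFF"`.
#' @param camera_model Camera model string.
#' @param exceptions Character vector of exception model names.
#' @return `"little"` or `"big"`.
#' @export
resolve_byte_order <- function(raw_image_type, camera_model = "",
                               exceptions = byte_order_exceptions()) {
  raw_image_type <- toupper(raw_image_type)
  if (!raw_image_type %in% c("PNG", "TIFF"))
    ir_stop(sprintf("unknown raw image type '%s'", raw_image_type),
            "ir_format_error")
  order <- if (raw_image_type == "PNG") "little" else "big"
  if (camera_model %in% exceptions)
    order <- if (order == "little") "big" else "little"
  order
}

.sidecar_csv <- function(path) {
  file.path(dirname(path),
            paste0(sub("\\.[^.]+$", "", basename(path)), ".csv"))
}

.is_sidecar <- function(path) {
  grepl("\\.(png|tif|tiff)$", path, ignore.case = TRUE) &&
    file.exists(.sidecar_csv(path))
}

.metadata_from_record <- function(rec, source_path) {
  structure(list(
    camera_model = as.character(rec$cameraModel),
    raw_image_type = toupper(as.character(rec$imageType)),
    cal = calibration_constants(G = rec$sensorG, O = rec$sensorO,
                                B = rec$sensorB, R = rec$sensorR,
                                F = rec$sensorF),
    atm = atmosphere_model(alpha1 = rec$atmAlpha1, alpha2 = rec$atmAlpha2,
                           beta1 = rec$atmBeta1, beta2 = rec$atmBeta2,
                           X = rec$atmX),
    user = acquisition_params(emissivity = rec$objEmissivity,
                              air_temp_C = rec$airTemp_C,
                              rel_humidity = rec$airRelHumidity_perc,
                              app_refl_temp_C = rec$appReflTemp_C,
                              distance_m = rec$objDistance_m),
    source_path = source_path,
    timestamp = if (!is.null(rec$timestamp)) as.character(rec$timestamp) else NA_character_),
    class = "image_metadata")
}

#' @export
print.image_metadata <- function(x, ...) {
  cat(sprintf("Radiometric image metadata (%s)\n", basename(x$source_path)))
  cat(sprintf("  camera: %s   payload: %s\n", x$camera_model, x$raw_image_type))
  print(x$cal); print(x$atm); print(x$user)
  invisible(x)
}

.exiftool_path <- function() Sys.which("exiftool")

.exiftool_json <- function(path) {
  et <- .exiftool_path()
  if (!nzchar(et))
    ir_stop("reading radiometric JPEGs requires the 'exiftool' utility on PATH; use sidecar fixtures otherwise",
            "ir_exiftool_missing")
  out <- suppressWarnings(system2(et, c("-j", "-n", shQuote(path)),
                                  stdout = TRUE, stderr = FALSE))
  js <- try(jsonlite::fromJSON(paste(out, collapse = "\n")), silent = TRUE)
  if (inherits(js, "try-error") || !is.data.frame(js) || nrow(js) < 1L)
    ir_stop(sprintf("'%s' is not a readable JPEG", path), "ir_format_error")
  as.list(js[1L, , drop = FALSE])
}

#' Extract metadata from a radiometric image
#'
#' Reads the camera-specific calibration constants, atmospheric model
#' coefficients and user-set acquisition parameters stored with a
#' radiometric image. For `.jpg`/`.jpeg` input the EXIF maker-note tags
#' are read through the external `exiftool` utility; for sidecar
#' fixtures (payload image plus one-row parameter CSV of the same base
#' name) the CSV is parsed directly. The input file is never modified.
#'
#' @param path Path to a radiometric JPEG or a sidecar payload image.
#' @param exceptions Byte-order exception model list (see
#'   [byte_order_exceptions()]); stored for downstream payload reading.
#' @return An object of class `image_metadata` with fields
#'   `camera_model`, `raw_image_type`, `cal`, `atm`, `user`,
#'   `source_path`, `timestamp`.
#' @export
extract_metadata <- function(path, exceptions = byte_order_exceptions()) {
  if (!file.exists(path))
    ir_stop(sprintf("file not found: '%s'", path), "ir_format_error")
  if (.is_sidecar(path)) {
    tab <- read_parameter_table(.sidecar_csv(path))
    return(.metadata_from_record(as.list(tab[1L, , drop = FALSE]), path))
  }
  if (!grepl("\\.jpe?g$", path, ignore.case = TRUE))
    ir_stop(sprintf("'%s' is neither a radiometric JPEG nor a sidecar fixture (missing parameter CSV?)", path),
            "ir_format_error")
  tags <- .exiftool_json(path)
  names(tags) <- gsub(" ", "", names(tags))
  rec <- list()
  for (tag in names(.exif_tag_map)) {
    field <- .exif_tag_map[[tag]]
    if (is.null(tags[[tag]])) {
      if (field %in% c("imageType", "cameraModel")) next
      ir_stop(sprintf("metadata incomplete: required tag '%s' missing in '%s'",
                      tag, path), "ir_metadata_error")
    }
    rec[[field]] <- tags[[tag]]
  }
  if (is.null(rec$imageType)) rec$imageType <- "PNG"
  if (is.null(rec$cameraModel)) rec$cameraModel <- ""
  # exiftool -n reports these tags in SI units: temperatures in C,
  # humidity as a fraction
  if (!is.null(tags$DateTimeOriginal)) rec$timestamp <- tags$DateTimeOriginal
  .metadata_from_record(rec, path)
}

#' Extract the raw 16-bit frame from a radiometric image
#'
#' Reads the embedded 16-bit payload and applies the resolved byte order
#' so the returned matrix holds true sensor digital numbers. For sidecar
#' fixtures the payload PNG/TIFF is read directly (float TIFF sidecars
#' return unquantized DN-valued reals and need no swapping).
#'
#' @param path Path to a radiometric JPEG or sidecar payload image.
#' @param byte_order `"little"` (byte-swap the stored samples) or
#'   `"big"` (use as stored); see [resolve_byte_order()].
#' @return Numeric matrix of digital numbers.
#' @export
extract_raw_frame <- function(path, byte_order = "big") {
  if (!file.exists(path))
    ir_stop(sprintf("file not found: '%s'", path), "ir_raw_missing")
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    m <- read_tiff_float(path)
    if (max(m, na.rm = TRUE) <= 1) m <- m * 65535  # integer-sample TIFF read scaled
    return(m)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stored <- try(read_png16(path), silent = TRUE)
    if (inherits(stored, "try-error"))
      ir_stop(sprintf("cannot read payload '%s': truncated or not a 16-bit grayscale PNG", path),
              "ir_format_error")
    dn <- if (identical(byte_order, "little")) swap16(stored) else stored
    return(dn)
  }
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    et <- .exiftool_path()
    if (!nzchar(et))
      ir_stop("extracting embedded payloads from JPEG requires 'exiftool' on PATH",
              "ir_exiftool_missing")
    tmp <- tempfile(fileext = ".bin")
    on.exit(unlink(tmp))
    status <- suppressWarnings(system2(
      et, c("-RawThermalImage", "-b", shQuote(path)),
      stdout = tmp, stderr = FALSE))
    if (!file.exists(tmp) || file.info(tmp)$size == 0L || !identical(status, 0L))
      ir_stop(sprintf("no embedded raw payload in '%s'", path),
              "ir_raw_missing")
    magic <- readBin(tmp, "raw", n = 4L)
    if (length(magic) >= 4L && all(magic[1:4] == as.raw(c(137, 80, 78, 71)))) {
      stored <- read_png16(tmp)
      dn <- if (identical(byte_order, "little")) swap16(stored) else stored
    } else {
      dn <- extract_raw_frame(tmp)  # TIFF payload
    }
    return(dn)
  }
  ir_stop(sprintf("unsupported payload container: '%s'", path),
          "ir_format_error")
}

#' Read and write per-image parameter tables
#'
#' Parameter tables hold one row per image with the full set of
#' calibration, atmospheric and user-set parameters under their
#' canonical column names (`filename`, `imageType`, `cameraModel`,
#' `sensorG`, `sensorO`, `sensorB`, `sensorF`, `sensorR`, `atmAlpha1`,
#' `atmAlpha2`, `atmBeta1`, `atmBeta2`, `atmX`, `appReflTemp_C`,
#' `airTemp_C`, `objEmissivity`, `airRelHumidity_perc`,
#' `objDistance_m`). Tables written by a processing run can be fed back
#' in to reproduce the identical results. Unknown extra columns are
#' preserved; the canonical columns keep their fixed order.
#'
#' @param path CSV file path.
#' @return `read_parameter_table()` returns a `data.frame`;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0L)
    ir_stop(sprintf("parameter table '%s' missing or empty", path),
            "ir_schema_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.param_columns, names(tab))
  if (length(missing) > 0L)
    ir_stop(sprintf("parameter table '%s' lacks required column(s): %s",
                    path, paste(missing, collapse = ", ")),
            "ir_schema_error")
  for (col in .param_numeric) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0L)
      ir_stop(sprintf("parameter table '%s': row %d, column '%s' is not numeric",
                      path, bad[1L], col), "ir_schema_error")
    tab[[col]] <- v
  }
  extra <- setdiff(names(tab), .param_columns)
  tab[, c(.param_columns, extra), drop = FALSE]
}

#' @rdname read_parameter_table
#' @param records `data.frame` of parameter records (one row per image).
#' @export
write_parameter_table <- function(records, path) {
  missing <- setdiff(.param_columns, names(records))
  if (length(missing) > 0L)
    ir_stop(sprintf("parameter records lack column(s): %s",
                    paste(missing, collapse = ", ")), "ir_schema_error")
  extra <- setdiff(names(records), .param_columns)
  records <- records[, c(.param_columns, extra), drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.record_from_metadata <- function(meta, filename) {
  data.frame(filename = filename,
             imageType = meta$raw_image_type,
             cameraModel = meta$camera_model,
             sensorG = meta$cal$G, sensorO = meta$cal$O, sensorB = meta$cal$B,
             sensorF = meta$cal$F, sensorR = meta$cal$R,
             atmAlpha1 = meta$atm$alpha1, atmAlpha2 = meta$atm$alpha2,
             atmBeta1 = meta$atm$beta1, atmBeta2 = meta$atm$beta2,
             atmX = meta$atm$X,
             appReflTemp_C = meta$user$app_refl_temp_C,
             airTemp_C = meta$user$air_temp_C,
             objEmissivity = meta$user$emissivity,
             airRelHumidity_perc = meta$user$rel_humidity * 100,
             objDistance_m = meta$user$distance_m,
             stringsAsFactors = FALSE)
}

#' Read and write temperature CSV grids
#'
#' Temperature frames are exported as plain CSV grids: one image row per
#' line, comma-separated, dot decimal, no header, two decimal places,
#' undefined pixels written as the token `NaN`. The fixed formatting
#' makes repeated runs byte-identical.
#'
#' @param frame Numeric matrix of temperatures (degrees C).
#' @param path CSV file path.
#' @param digits Decimal places to print (default 2).
#' @return `read_temperature_csv()` returns a numeric matrix;
#'   `write_temperature_csv()` returns `path` invisibly.
#' @export
write_temperature_csv <- function(frame, path, digits = 2L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    ir_stop("temperature frame must be a numeric matrix", "ir_format_error")
  fmt <- sprintf("%%.%df", digits)
  txt <- apply(frame, 1L, function(row) {
    s <- sprintf(fmt, row)
    s[is.nan(row) | is.na(row)] <- "NaN"
    paste(s, collapse = ",")
  })
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0L)
    ir_stop(sprintf("temperature CSV '%s' missing or empty", path),
            "ir_format_error")
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L)
    ir_stop(sprintf("temperature CSV '%s' is empty", path), "ir_format_error")
  rows <- strsplit(ln, ",", fixed = TRUE)
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    ir_stop(sprintf("temperature CSV '%s' has ragged rows", path),
            "ir_format_error")
  matrix(suppressWarnings(as.numeric(unlist(rows))),
         nrow = length(rows), byrow = TRUE)
}
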