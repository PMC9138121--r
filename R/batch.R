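# Batch processing: apply the raw-to-temperature chain to every
# radiometric image in a folder under one of three parameterization
# modes, writing reproducible outputs:
#   raw/<name>.png    16-bit raw digital numbers
#   temp/<name>.tif   32-bit float temperatures (degrees C)
#   color/<name>.png  false-color rendering
#   text/<name>.csv   temperatures as text (2 decimals; byte-stable)
#   parameters.csv    the parameters used, one row per image — feed it
#                     back with mode = "file" to reproduce the run

.discover_inputs <- function(folder) {
  all <- list.files(folder, full.names = TRUE)
  jpgs <- all[grepl("\\.jpe?g$", all, ignore.case = TRUE)]
  side <- all[grepl("\\.(png|tif|tiff)$", all, ignore.case = TRUE)]
  side <- side[vapply(side, .is_sidecar, logical(1))]
  sort(c(jpgs, side))
}

.base_name <- function(path) sub("\\.[^.]+$", "", basename(path))

#' Process a folder of radiometric images
#'
#' Runs the full raw-signal-to-temperature chain on every radiometric
#' JPEG (or sidecar fixture pair) in `folder`, writing four outputs per
#' image into subfolders `raw/`, `temp/`, `color/`, `text/` plus one
#' `parameters.csv` for the run. Numeric output formatting is fixed, so
#' identical inputs and parameters give byte-identical temperature CSVs.
#'
#' Parameterization modes:
#' \describe{
#'   \item{`"stored"`}{each image uses the user-set parameters stored in
#'     its own metadata;}
#'   \item{`"global"`}{the supplied [acquisition_params()] replace the
#'     user-set fields for all images (calibration constants still come
#'     from each image's own metadata);}
#'   \item{`"file"`}{each image's row in a parameter table (CSV, see
#'     [read_parameter_table()]) supplies its user-set fields — the
#'     reproducibility mode.}
#' }
#'
#' A failing image does not abort the batch: it is recorded in the
#' manifest with its error and processing continues.
#'
#' @param folder Folder containing the input images.
#' @param mode `"stored"`, `"global"` or `"file"`.
#' @param params [acquisition_params()] for `mode = "global"`.
#' @param params_file Parameter-table CSV path for `mode = "file"`.
#' @param palette,contrast Rendering options for the false-color output.
#' @param compat_first_file If `TRUE`, copy the first image's
#'   calibration constants and atmosphere model to all images (strict
#'   compatibility with tools that extract metadata only once per
#'   folder). Default `FALSE`: constants always come from each image,
#'   which is the only safe choice when a folder mixes cameras.
#' @param exceptions Byte-order exception model list.
#' @return Invisibly, a manifest `data.frame` with one row per input:
#'   `input`, `status` (`"ok"`/`"failed"`), `error`, `undefined_pixels`
#'   and the four output paths. The parameter table used is attached as
#'   attribute `parameters`, its path as attribute `parameters_csv`.
#' @export
process_folder <- function(folder,
                           mode = c("stored", "global", "file"),
                           params = NULL, params_file = NULL,
                           palette = "inferno", contrast = "normal",
                           compat_first_file = FALSE,
                           exceptions = byte_order_exceptions()) {
  mode <- match.arg(mode)
  inputs <- .discover_inputs(folder)
  if (length(inputs) == 0L)
    ir_stop(sprintf("no radiometric images found in '%s'", folder),
            "ir_nothing_to_process")
  if (mode == "global" && !inherits(params, "acquisition_params"))
    ir_stop("mode = \"global\" needs an acquisition_params object",
            "ir_parameter_error")
  ptab <- NULL
  if (mode == "file") {
    if (is.null(params_file))
      ir_stop("mode = \"file\" needs a params_file path", "ir_parameter_error")
    ptab <- read_parameter_table(params_file)
    known <- .base_name(ptab$filename) %in% .base_name(inputs)
    if (any(!known))
      ir_warn(sprintf("parameter rows with no matching image skipped: %s",
                      paste(ptab$filename[!known], collapse = ", ")),
              "ir_orphan_parameter_row")
  }
  for (sub in c("raw", "temp", "color", "text"))
    dir.create(file.path(folder, sub), showWarnings = FALSE)

  n <- length(inputs)
  manifest <- data.frame(input = inputs, status = "ok", error = "",
                         undefined_pixels = 0L,
                         raw_png = "", temp_tiff = "", color_png = "",
                         temp_csv = "", stringsAsFactors = FALSE)
  records <- vector("list", n)
  first_meta <- NULL

  for (i in seq_len(n)) {
    path <- inputs[i]
    nm <- .base_name(path)
    res <- tryCatch({
      meta <- extract_metadata(path, exceptions)
      if (compat_first_file) {
        if (is.null(first_meta)) first_meta <- meta
        meta$cal <- first_meta$cal
        meta$atm <- first_meta$atm
      }
      user <- switch(mode,
        stored = meta$user,
        global = params,
        file = {
          row <- ptab[.base_name(ptab$filename) == nm, , drop = FALSE]
          if (nrow(row) == 0L)
            ir_stop(sprintf("no parameter row for image '%s'", nm),
                    "ir_missing_parameter_row")
          acquisition_params(row$objEmissivity[1], row$airTemp_C[1],
                             row$airRelHumidity_perc[1],
                             row$appReflTemp_C[1], row$objDistance_m[1])
        })
      order <- resolve_byte_order(meta$raw_image_type, meta$camera_model,
                                  exceptions)
      raw <- extract_raw_frame(path, order)
      temp <- suppressMessages(
        frame_to_temperature(raw, user, meta$cal, meta$atm))

      raw_png <- file.path(folder, "raw", paste0(nm, ".png"))
      if (all(raw == round(raw))) write_png16(raw, raw_png) else raw_png <- ""
      temp_tiff <- file.path(folder, "temp", paste0(nm, ".tif"))
      write_tiff_float(temp, temp_tiff)
      rng <- compute_display_range(temp, contrast)
      color_png <- file.path(folder, "color", paste0(nm, ".png"))
      png::writePNG(suppressMessages(apply_palette(temp, rng, palette)),
                    color_png)
      temp_csv <- file.path(folder, "text", paste0(nm, ".csv"))
      write_temperature_csv(temp, temp_csv)

      meta$user <- user
      records[[i]] <- .record_from_metadata(meta, basename(path))
      list(undef = attr(temp, "undefined_pixels"),
           paths = c(raw_png, temp_tiff, color_png, temp_csv))
    }, irproc_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[i] <- "failed"
      manifest$error[i] <- conditionMessage(res)
      ir_warn(sprintf("skipping '%s': %s", basename(path),
                      conditionMessage(res)), "ir_image_failed")
    } else {
      manifest$undefined_pixels[i] <- res$undef
      manifest[i, c("raw_png", "temp_tiff", "color_png", "temp_csv")] <-
        as.list(res$paths)
    }
  }
  if (all(manifest$status == "failed"))
    ir_stop("all images in the folder failed to process", "ir_fatal_error")
  ptab_out <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  params_csv <- file.path(folder, "parameters.csv")
  write_parameter_table(ptab_out, params_csv)
  attr(manifest, "parameters") <- ptab_out
  attr(manifest, "parameters_csv") <- params_csv
  class(manifest) <- c("run_manifest", "data.frame")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  ok <- sum(x$status == "ok")
  cat(sprintf("Processing run: %d image(s), %d ok, %d failed\n",
              nrow(x), ok, nrow(x) - ok))
  if (any(x$undefined_pixels > 0))
    cat(sprintf("  undefined pixels: %s\n",
                paste(sprintf("%s=%d", basename(x$input), x$undefined_pixels)[
                  x$undefined_pixels > 0], collapse = ", ")))
  cat(sprintf("  parameters: %s\n", attr(x, "parameters_csv")))
  invisible(x)
}

#' Reproduce a processing run from its saved parameter table
#'
#' Delegates to [process_folder()] with `mode = "file"`. Because output
#' formatting is fixed, the temperature CSVs of the reproduced run are
#' byte-identical to the original run's.
#'
#' @param params_csv Path to a `parameters.csv` written by a previous run.
#' @param folder Folder containing the input images.
#' @param ... Further arguments passed to [process_folder()].
#' @return The run manifest, invisibly.
#' @export
reprocess_from_manifest <- function(params_csv, folder, ...) {
  process_folder(folder, mode = "file", params_file = params_csv, ...)
}
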