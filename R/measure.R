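# Reproducible per-object temperature statistics over image sets, using
# an 8-bit label mask: 0 = background (unmeasured), 1..255 = object ids.

#' Load or save an 8-bit label mask
#'
#' Masks are single-channel 8-bit PNG images whose pixel values assign
#' each pixel to an object (1-255) or to the background (0). A mask can
#' be produced here from a thresholded image ([threshold_to_mask()]) or
#' drawn in any external image editor.
#'
#' @param path PNG file path.
#' @return `load_mask()` returns an integer matrix in [0, 255];
#'   `save_mask()` returns `path` invisibly.
#' @export
load_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L)
    ir_stop(sprintf("mask '%s' has %d channels; flatten it to single-channel 8-bit grayscale first",
                    path, dim(img)[3]), "ir_format_error")
  mask <- round(img * 255)
  if (any(mask != round(img * 255)) || any(mask < 0 | mask > 255))
    ir_stop(sprintf("mask '%s' is not 8-bit", path), "ir_format_error")
  storage.mode(mask) <- "integer"
  if (all(mask == 0L))
    ir_warn("mask contains no labelled objects", "ir_empty_mask")
  mask
}

#' @rdname load_mask
#' @param mask Integer matrix with values in [0, 255].
#' @export
save_mask <- function(mask, path) {
  if (!is.matrix(mask) || any(mask < 0 | mask > 255) || any(mask != round(mask)))
    ir_stop("mask must be an integer matrix with values in [0, 255]",
            "ir_format_error")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Convert a thresholded binary image to a sequentially labelled mask
#'
#' Mirrors the common leaf-measurement workflow: threshold a temperature
#' frame (e.g., leaves cooler than background), then label each
#' connected foreground region 1, 2, ... in scan order. Connected
#' component labelling is delegated to the EBImage package.
#'
#' @param binary Logical or 0/1 matrix; `TRUE`/1 marks object pixels.
#' @return Integer label mask (values 0..n objects).
#' @export
threshold_to_mask <- function(binary) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    ir_stop("threshold_to_mask requires the EBImage package",
            "ir_dependency_error")
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(b))))
  lab <- t(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  if (max(lab) > 255L)
    ir_stop(sprintf("thresholding produced %d objects; a label mask holds at most 255",
                    max(lab)), "ir_parameter_error")
  lab
}

#' Measure per-object temperature statistics
#'
#' For every image and every object label present in the mask, computes
#' the mean, minimum, maximum and standard deviation of the temperatures
#' over the object's pixels. Undefined (`NaN`) pixels are excluded from
#' the statistics; a label whose pixels are all undefined in a frame
#' yields a record with `pixel_count = 0` and `NA` statistics (reported
#' with a message). The standard deviation uses the population formula
#' (divide by n), so a single-pixel object has `sd = 0`.
#'
#' @param frames A temperature matrix, or a named list of them (names
#'   are the image ids; unnamed lists get ids `frame1`, `frame2`, ...).
#' @param mask Integer label mask matrix (values 0-255, 0 = background)
#'   with the same dimensions as every frame.
#' @return A `data.frame` with columns `image`, `label`, `mean`, `min`,
#'   `max`, `sd`, `pixel_count`, ordered by image then ascending label.
#' @export
measure_objects <- function(frames, mask) {
  if (is.matrix(frames)) frames <- list(frame1 = frames)
  if (is.null(names(frames)) || any(!nzchar(names(frames))))
    names(frames) <- sprintf("frame%d", seq_along(frames))
  if (!is.matrix(mask) || any(mask < 0 | mask > 255))
    ir_stop("mask must be a matrix with values in [0, 255]",
            "ir_format_error")
  labels <- sort(unique(as.integer(mask[mask > 0])))
  out <- vector("list", length(frames) * max(1L, length(labels)))
  k <- 0L
  for (id in sort(names(frames))) {
    fr <- frames[[id]]
    if (!identical(dim(fr), dim(mask)))
      ir_stop(sprintf("mask dimensions do not match frame '%s'", id),
              "ir_dimension_error")
    for (lab in labels) {
      v <- fr[mask == lab]
      v <- v[!is.na(v)]
      k <- k + 1L
      if (length(v) == 0L) {
        message(sprintf("label %d has no defined pixels in image '%s'",
                        lab, id))
        out[[k]] <- data.frame(image = id, label = lab, mean = NA_real_,
                               min = NA_real_, max = NA_real_, sd = NA_real_,
                               pixel_count = 0L)
      } else {
        m <- mean(v)
        out[[k]] <- data.frame(
          image = id, label = lab, mean = m, min = min(v), max = max(v),
          sd = sqrt(sum((v - m)^2) / length(v)),  # population sd; n=1 -> 0
          pixel_count = length(v))
      }
    }
  }
  if (k == 0L)
    return(data.frame(image = character(), label = integer(),
                      mean = numeric(), min = numeric(), max = numeric(),
                      sd = numeric(), pixel_count = integer()))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Measure objects over a processed folder
#'
#' Applies [measure_objects()] to every temperature CSV under the
#' `text/` subfolder of a processed image folder and (optionally) writes
#' the combined measurement table.
#'
#' @param folder A folder previously processed with [process_folder()].
#' @param mask Label mask matrix or path to a mask PNG.
#' @param out Optional output CSV path; defaults to
#'   `measurements.csv` in `folder`.
#' @return The measurement `data.frame`, invisibly.
#' @export
measure_folder <- function(folder, mask, out = file.path(folder, "measurements.csv")) {
  if (is.character(mask)) mask <- load_mask(mask)
  text_dir <- file.path(folder, "text")
  files <- sort(list.files(text_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L)
    ir_stop(sprintf("no temperature CSVs under '%s'; run process_folder() first",
                    text_dir), "ir_nothing_to_process")
  frames <- lapply(files, read_temperature_csv)
  names(frames) <- sub("\\.csv$", "", basename(files))
  res <- measure_objects(frames, mask)
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  invisible(res)
}
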