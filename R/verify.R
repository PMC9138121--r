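# Pixelwise comparison of produced temperature grids against reference
# exports from other software, reporting mean and maximum absolute
# differences per image and overall, with a scatter plot per image.

#' Read a reference temperature CSV export
#'
#' Vendor exports vary in dialect: the separator (comma or semicolon)
#' and, with semicolons, often a decimal comma. Both are auto-detected.
#' Undefined cells (empty or `NaN`) read as `NaN`.
#'
#' @param path CSV file path.
#' @return Numeric matrix of temperatures (degrees C).
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0L)
    ir_stop(sprintf("reference CSV '%s' missing or empty", path),
            "ir_format_error")
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln)]
  sep <- if (any(grepl(";", ln, fixed = TRUE))) ";" else ","
  if (sep == ";") ln <- gsub(",", ".", ln, fixed = TRUE)  # decimal commas
  rows <- strsplit(ln, sep, fixed = TRUE)
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    ir_stop(sprintf("reference CSV '%s' has ragged rows", path),
            "ir_format_error")
  matrix(suppressWarnings(as.numeric(unlist(rows))),
         nrow = length(rows), byrow = TRUE)
}

#' Compare produced temperatures against reference exports
#'
#' Matches produced and reference temperature CSVs by file name,
#' computes per-pixel absolute differences over the pixels defined in
#' both grids, and reports per-image and overall mean and maximum
#' differences. Pixels where the reference sits exactly at -40.00
#' degrees C while the produced value is lower are counted separately
#' (`floor_pixels`): some vendor software clamps its output at -40
#' degrees C, so such pixels disagree by construction, not by error.
#' Optionally writes a text report and one scatter plot per image.
#'
#' @param produced Folder of produced temperature CSVs (e.g., the
#'   `text/` subfolder of a processed run) or a character vector of
#'   files.
#' @param reference Folder (or files) of reference CSVs with matching
#'   base names.
#' @param out_dir If non-`NULL`, write `comparison_report.txt` and
#'   `scatter_<name>.png` files here.
#' @return A `comparison_report` object: list with `per_image`
#'   (data.frame: `image`, `n`, `mean_abs_diff`, `max_abs_diff`,
#'   `skipped_undefined`, `floor_pixels`), `overall` (list with `n`,
#'   `mean_abs_diff`, `max_abs_diff`) and `artifacts` (paths written).
#' @export
compare_to_reference <- function(produced, reference, out_dir = NULL) {
  expand <- function(x) {
    if (length(x) == 1L && dir.exists(x))
      sort(list.files(x, pattern = "\\.csv$", full.names = TRUE))
    else x
  }
  pfiles <- expand(produced)
  rfiles <- expand(reference)
  names(pfiles) <- .base_name(pfiles)
  names(rfiles) <- .base_name(rfiles)
  common <- intersect(names(pfiles), names(rfiles))
  if (length(common) == 0L)
    ir_stop("no produced/reference file pairs with matching names",
            "ir_nothing_to_process")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  rows <- list(); artifacts <- character(0)
  abs_sum <- 0; abs_n <- 0; abs_max <- 0
  for (nm in sort(common)) {
    p <- read_temperature_csv(pfiles[[nm]])
    r <- read_reference_csv(rfiles[[nm]])
    if (!identical(dim(p), dim(r))) {
      ir_warn(sprintf("dimension mismatch for '%s' (%dx%d vs %dx%d); skipped",
                      nm, nrow(p), ncol(p), nrow(r), ncol(r)),
              "ir_dimension_error")
      next
    }
    ok <- !is.na(p) & !is.na(r)
    floor_px <- sum(ok & r == -40 & p < -40)
    use <- ok & !(r == -40 & p < -40)
    d <- abs(p[use] - r[use])
    rows[[nm]] <- data.frame(
      image = nm, n = sum(use),
      mean_abs_diff = if (sum(use)) mean(d) else NA_real_,
      max_abs_diff = if (sum(use)) max(d) else NA_real_,
      skipped_undefined = sum(!ok), floor_pixels = floor_px)
    abs_sum <- abs_sum + sum(d); abs_n <- abs_n + length(d)
    abs_max <- max(abs_max, if (length(d)) max(d) else 0)
    if (!is.null(out_dir)) {
      plot_path <- file.path(out_dir, sprintf("scatter_%s.png", nm))
      grDevices::png(plot_path, width = 600, height = 600)
      graphics::plot(r[use], p[use], pch = ".",
                     xlab = "reference temperature (C)",
                     ylab = "produced temperature (C)",
                     main = sprintf("%s: mean |diff| = %.4f C, max = %.4f C",
                                    nm, mean(d), max(d)))
      graphics::abline(0, 1, col = "red")
      grDevices::dev.off()
      artifacts <- c(artifacts, plot_path)
    }
  }
  if (length(rows) == 0L)
    ir_stop("no comparable image pairs (all mismatched)", "ir_fatal_error")
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  overall <- list(n = abs_n, mean_abs_diff = abs_sum / abs_n,
                  max_abs_diff = abs_max)
  report <- structure(list(per_image = per_image, overall = overall,
                           artifacts = artifacts),
                      class = "comparison_report")
  if (!is.null(out_dir)) {
    txt_path <- file.path(out_dir, "comparison_report.txt")
    writeLines(format_comparison_report(report), txt_path)
    report$artifacts <- c(txt_path, artifacts)
  }
  report
}

format_comparison_report <- function(report) {
  pi <- report$per_image
  c("Temperature comparison against reference exports",
    "",
    sprintf("%-24s %10s %16s %16s %10s %8s", "image", "pixels",
            "mean |diff| (C)", "max |diff| (C)", "skipped", "floored"),
    sprintf("%-24s %10d %16.4f %16.4f %10d %8d", pi$image, pi$n,
            pi$mean_abs_diff, pi$max_abs_diff, pi$skipped_undefined,
            pi$floor_pixels),
    "",
    sprintf("Overall: %d pixels, mean |diff| = %.4f C, max |diff| = %.4f C",
            report$overall$n, report$overall$mean_abs_diff,
            report$overall$max_abs_diff))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_comparison_report(x), sep = "\n")
  invisible(x)
}
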