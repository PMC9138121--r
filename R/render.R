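# Quantitatively accurate false-color rendering: histogram-stretched
# display ranges, LUT application, scale bars and video export. Rendered
# colors are exact LUT entries, so a rendered image can be decoded back
# to temperature within one LUT bin width.

.render_env <- new.env(parent = emptyenv())

#' Color lookup tables
#'
#' Returns a 256 x 3 integer matrix of RGB values (0-255). `"inferno"`
#' is the perceptually uniform, color-blind-safe thermal palette bundled
#' with the package (dark blue through red and yellow); `"greyscale"`
#' maps cold to black and warm to white. Both have monotonically
#' non-decreasing luma, so they survive black-and-white reproduction.
#'
#' @param name `"inferno"` or `"greyscale"`.
#' @return 256 x 3 integer matrix, columns r, g, b.
#' @export
palette_lut <- function(name = c("inferno", "greyscale")) {
  name <- match.arg(name)
  key <- paste0("lut_", name)
  if (!is.null(.render_env[[key]])) return(.render_env[[key]])
  lut <- if (name == "greyscale") {
    cbind(r = 0:255, g = 0:255, b = 0:255)
  } else {
    as.matrix(utils::read.csv(system.file("extdata", "inferno_lut.csv",
                                          package = "irproc")))
  }
  storage.mode(lut) <- "integer"
  .render_env[[key]] <- lut
  lut
}

#' Compute a display range by histogram stretching
#'
#' Picks the displayed temperature range by excluding a stated total
#' fraction of extreme pixels (the histogram "tails"): 0% for low
#' contrast, 0.3% for normal, 3% for high. The excluded count
#' `m = round(n * f)` is split `floor(m/2)` from the cold tail and
#' `ceiling(m/2)` from the hot tail (the odd pixel goes to the hot tail,
#' where outliers such as specular sun glint typically sit), so exactly
#' the stated fraction of distinct-valued pixels falls outside the
#' range. A constant (or fully tied) input yields a degenerate range and
#' is expanded by +/- 0.5 degrees C with a warning.
#'
#' @param values Numeric vector or matrix of temperatures (degrees C);
#'   `NaN`/`NA` pixels are ignored. Pool several frames' values for a
#'   set-wide (global-scope) range.
#' @param contrast `"low"`, `"normal"` or `"high"`.
#' @return An object of class `display_range`: list with `t_min`,
#'   `t_max`, `contrast`.
#' @export
compute_display_range <- function(values, contrast = c("normal", "low", "high")) {
  contrast <- match.arg(contrast)
  v <- as.vector(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L)
    ir_stop("display range needs at least two defined pixel values",
            "ir_parameter_error")
  f <- switch(contrast, low = 0, normal = 0.003, high = 0.03)
  s <- sort(v)
  n <- length(s)
  m <- round(n * f)
  k_lo <- m %/% 2L
  k_hi <- m - k_lo
  t_min <- s[k_lo + 1L]
  t_max <- s[n - k_hi]
  if (!(t_min < t_max)) {
    t_min <- s[1L]; t_max <- s[n]
  }
  if (!(t_min < t_max)) {
    ir_warn("constant image: display range expanded by +/- 0.5 C",
            "ir_degenerate_range")
    t_min <- t_min - 0.5; t_max <- t_max + 0.5
  }
  structure(list(t_min = t_min, t_max = t_max, contrast = contrast),
            class = "display_range")
}

#' @export
print.display_range <- function(x, ...) {
  cat(sprintf("Display range [%.2f, %.2f] C (%s contrast)\n",
              x$t_min, x$t_max, x$contrast))
  invisible(x)
}

#' Display ranges for a set of frames
#'
#' With `"global"` scope all frames are pooled into one shared range, so
#' a given temperature is rendered with the same color in every image of
#' the set (best for comparing images). With `"per-image"` scope each
#' frame gets its own range (best for seeing within-image differences).
#'
#' @param frames List of temperature matrices.
#' @param contrast Contrast level, see [compute_display_range()].
#' @param scope `"global"` or `"per-image"`.
#' @return List of `display_range` objects, one per frame (identical
#'   objects under global scope).
#' @export
display_ranges <- function(frames, contrast = "normal",
                           scope = c("global", "per-image")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    rng <- compute_display_range(unlist(lapply(frames, as.vector)), contrast)
    rep(list(rng), length(frames))
  } else {
    lapply(frames, compute_display_range, contrast = contrast)
  }
}

.palette_index <- function(frame, range) {
  # 0-based LUT index; linear map with half-open bins, last bin closed.
  # The exact midpoint of the range lands in bin 128 (upper-bin tie-break).
  w <- (range$t_max - range$t_min) / 256
  idx <- floor((frame - range$t_min) / w)
  idx <- pmin(pmax(idx, 0), 255)
  idx[is.na(frame)] <- 0          # undefined pixels take the palette minimum
  idx
}

#' Render a temperature frame as a false-color image
#'
#' Linearly maps `[t_min, t_max]` onto the 256-entry LUT (values outside
#' the range are clamped to the end colors; undefined pixels take the
#' first LUT color, with a message reporting their count). Every
#' rendered pixel is an exact LUT entry, so [decode_rendered()] recovers
#' its temperature to within one bin width `(t_max - t_min) / 256`.
#'
#' @param frame Temperature matrix (degrees C).
#' @param range A `display_range` from [compute_display_range()].
#' @param palette Palette name, see [palette_lut()].
#' @return `height x width x 3` numeric array with values in [0, 1].
#' @export
apply_palette <- function(frame, range, palette = "inferno") {
  stopifnot(inherits(range, "display_range"))
  lut <- palette_lut(palette)
  n_bad <- sum(is.na(frame))
  if (n_bad > 0L)
    message(sprintf("apply_palette: %d undefined pixel(s) rendered as palette minimum",
                    n_bad))
  idx <- .palette_index(frame, range)
  rgb <- array(0, c(nrow(frame), ncol(frame), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(lut[idx + 1L, ch], nrow(frame)) / 255
  rgb
}

#' Decode a rendered false-color image back to temperatures
#'
#' Maps each pixel's RGB color to its LUT index (exact match against the
#' palette) and returns the bin-centre temperature. For images produced
#' by [apply_palette()] the decoding error of every in-range defined
#' pixel is below `(t_max - t_min) / 256`.
#'
#' @param rgb `height x width x 3` array in [0, 1].
#' @param range The `display_range` used for rendering.
#' @param palette The palette used for rendering.
#' @return Temperature matrix (degrees C, bin centres).
#' @export
decode_rendered <- function(rgb, range, palette = "inferno") {
  lut <- palette_lut(palette) / 255
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]))
  # nearest LUT entry (squared distance); renders are exact entries
  d2 <- outer(px[, 1], lut[, 1], "-")^2 + outer(px[, 2], lut[, 2], "-")^2 +
    outer(px[, 3], lut[, 3], "-")^2
  idx <- max.col(-d2, ties.method = "first") - 1L
  wbin <- (range$t_max - range$t_min) / 256
  matrix(range$t_min + (idx + 0.5) * wbin, h, w)
}

# 3x5 bitmap glyphs for scale-bar labels
.glyphs <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","001","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  "-" = c("000","000","111","000","000"), "." = c("000","000","000","000","010"),
  "C" = c("111","100","100","100","111"), " " = c("000","000","000","000","000"))

.draw_text <- function(rgb, text, row, col, scale = 1L, color = c(1, 1, 1)) {
  chars <- strsplit(text, "")[[1]]
  x <- col
  for (ch in chars) {
    g <- .glyphs[[ch]]
    if (is.null(g)) g <- .glyphs[[" "]]
    for (gy in 1:5) {
      bits <- strsplit(g[gy], "")[[1]] == "1"
      for (gx in 1:3) {
        if (!bits[gx]) next
        rr <- row + (gy - 1L) * scale + seq_len(scale) - 1L
        cc <- x + (gx - 1L) * scale + seq_len(scale) - 1L
        rr <- rr[rr >= 1 & rr <= nrow(rgb)]
        cc <- cc[cc >= 1 & cc <= ncol(rgb)]
        for (ch3 in 1:3) rgb[rr, cc, ch3] <- color[ch3]
      }
    }
    x <- x + 4L * scale
  }
  rgb
}

#' Add a temperature scale bar to a rendered image
#'
#' Draws a vertical color bar rendering the full LUT (warmest color on
#' top) along the right edge, with the range maximum labelled above and
#' the minimum below, both at one decimal place. Pixels outside the bar
#' region are untouched.
#'
#' @param rgb `height x width x 3` array from [apply_palette()].
#' @param range The `display_range` used for rendering.
#' @param palette Palette name.
#' @param size `"small"` or `"large"` (bar width and font size).
#' @return The annotated RGB array.
#' @export
add_scale_bar <- function(rgb, range, palette = "inferno",
                          size = c("small", "large")) {
  size <- match.arg(size)
  lut <- palette_lut(palette) / 255
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  sc <- if (size == "small") 1L else 2L
  bar_w <- 6L * sc
  margin <- 2L * sc
  label_h <- 5L * sc + margin
  bar_h <- h - 2L * (label_h + margin)
  label_w <- 7L * 4L * sc  # up to 7 characters
  need_w <- bar_w + 2L * margin
  if (bar_h < 16L || w < max(need_w, label_w + margin))
    ir_stop(sprintf("image (%dx%d) too small to host a %s scale bar%s",
                    w, h, size,
                    if (size == "large") "; try size = \"small\"" else ""),
            "ir_render_error")
  top <- label_h + margin
  cols <- (w - margin - bar_w + 1L):(w - margin)
  # warmest at the top
  idx <- rev(round(seq(0, 255, length.out = bar_h)))
  for (ch in 1:3)
    rgb[top + seq_len(bar_h) - 1L, cols, ch] <- matrix(lut[idx + 1L, ch],
                                                       bar_h, bar_w)
  lab_max <- sprintf("%.1f", range$t_max)
  lab_min <- sprintf("%.1f", range$t_min)
  col_max <- max(1L, w - margin - nchar(lab_max) * 4L * sc)
  col_min <- max(1L, w - margin - nchar(lab_min) * 4L * sc)
  rgb <- .draw_text(rgb, lab_max, margin, col_max, sc)
  rgb <- .draw_text(rgb, lab_min, top + bar_h + margin, col_min, sc)
  rgb
}

#' Export rendered frames as a video file
#'
#' Writes an uncompressed RGB AVI (RIFF container, DIB frames): a
#' lossless, deterministic encoding readable by common players and
#' analysis tools. All frames must share the same dimensions.
#'
#' @param frames List of `height x width x 3` RGB arrays in [0, 1], in
#'   playback order.
#' @param path Output file path (conventionally `.avi`).
#' @param fps Frames per second (default 10).
#' @return `path`, invisibly.
#' @export
export_video <- function(frames, path, fps = 10) {
  if (length(frames) < 1L)
    ir_stop("video export needs at least one frame", "ir_render_error")
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(dims)) != 1L)
    ir_stop("video frames have mixed dimensions", "ir_render_error")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  frame_bytes <- row_bytes * h
  n <- length(frames)

  frame_raw <- function(f) {
    # BGR, bottom-up rows, each padded to a 4-byte boundary
    b <- array(0L, c(h, w, 3L))
    for (ch in 1:3) b[, , ch] <- round(pmin(pmax(f[, , 4L - ch], 0), 1) * 255)
    out <- raw(frame_bytes)
    for (r in seq_len(h)) {
      src <- h - r + 1L                       # bottom-up
      px <- as.vector(rbind(b[src, , 1L], b[src, , 2L], b[src, , 3L]))
      out[(r - 1L) * row_bytes + seq_along(px)] <- as.raw(px)
    }
    out
  }

  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  fcc <- charToRaw
  chunk <- function(id, data) c(fcc(id), u32(length(data)), data,
                                if (length(data) %% 2L) as.raw(0L))
  list_chunk <- function(type, data) chunk("LIST", c(fcc(type), data))

  avih <- c(u32(round(1e6 / fps)), u32(frame_bytes * fps), u32(0L),
            u32(16L),                    # AVIF_HASINDEX
            u32(n), u32(0L), u32(1L), u32(frame_bytes),
            u32(w), u32(h), u32(0L), u32(0L), u32(0L), u32(0L))
  strh <- c(fcc("vids"), fcc("DIB "), u32(0L), u16(0L), u16(0L), u32(0L),
            u32(1L), u32(round(fps)), u32(0L), u32(n), u32(frame_bytes),
            u32(-1L), u32(0L), u16(0L), u16(0L), u16(w), u16(h))
  strf <- c(u32(40L), u32(w), u32(h), u16(1L), u16(24L), u32(0L),
            u32(frame_bytes), u32(0L), u32(0L), u32(0L), u32(0L))
  hdrl <- list_chunk("hdrl", c(chunk("avih", avih),
                               list_chunk("strl", c(chunk("strh", strh),
                                                    chunk("strf", strf)))))
  movi_frames <- raw(0)
  idx <- raw(0)
  offset <- 4L
  for (i in seq_len(n)) {
    fr <- chunk("00db", frame_raw(frames[[i]]))
    movi_frames <- c(movi_frames, fr)
    idx <- c(idx, fcc("00db"), u32(16L), u32(offset), u32(frame_bytes))
    offset <- offset + length(fr)
  }
  movi <- list_chunk("movi", movi_frames)
  idx1 <- chunk("idx1", idx)
  body <- c(fcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

# Minimal AVI header parser (frame count / dimensions), for validation.
read_avi_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) ir_stop("not a RIFF file", "ir_format_error")
  invisible(readBin(con, "integer", size = 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "AVI "))
    ir_stop("not an AVI file", "ir_format_error")
  # LIST hdrl
  readChar(con, 4L, useBytes = TRUE); readBin(con, "integer", size = 4L,
                                              endian = "little")
  readChar(con, 4L, useBytes = TRUE)  # 'hdrl'
  readChar(con, 4L, useBytes = TRUE)  # 'avih'
  readBin(con, "integer", size = 4L, endian = "little")
  a <- readBin(con, "integer", n = 14L, size = 4L, endian = "little")
  list(fps = round(1e6 / a[1]), frames = a[5], width = a[9], height = a[10])
}
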