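# Compact raster writers for the two output formats the toolchain needs
# exactly: 16-bit grayscale PNG (raw digital numbers) and uncompressed
# 32-bit float TIFF (temperatures in degrees C). Readback goes through
# png::readPNG / tiff::readTIFF, which both handle these encodings.

# CRC-32 (PNG chunk checksums), table-driven. R's bitw* operate on the
# 32-bit two's-complement pattern with logical shifts, which is what the
# algorithm needs; 0xEDB88320 is -306674912L in that representation.
.crc_table <- local({
  tbl <- integer(256)
  poly <- -306674912L
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) == 1L)
        bitwXor(poly, bitwShiftR(cc, 1L)) else bitwShiftR(cc, 1L)
    }
    tbl[n + 1L] <- cc
  }
  tbl
})

.crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  .crc_table[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L])
  }
  bitwXor(cc, -1L)
}

.u32be <- function(x) {
  # unsigned 32-bit big-endian bytes from a double-valued count
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32be(length(data)), body, writeBin(.crc32(body), raw(), size = 4L,
                                         endian = "big"))
}

#' Write a 16-bit grayscale PNG
#'
#' Stores a matrix of digital numbers (integers in [0, 65535]) as a
#' 16-bit single-channel PNG. `png::readPNG(path) * 65535` recovers the
#' matrix exactly.
#'
#' @param dn Numeric matrix of integers in [0, 65535]; `dn[row, col]`
#'   is the pixel at image row `row`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(dn, path) {
  .check_raw_frame(dn)
  if (any(dn != round(dn)))
    ir_stop("16-bit PNG requires integer digital numbers", "ir_format_error")
  h <- nrow(dn); w <- ncol(dn)
  ihdr <- c(.u32be(w), .u32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  m <- t(dn)                               # columns of m = image rows
  hi <- as.raw(m %/% 256); lo <- as.raw(m %% 256)
  samp <- as.vector(rbind(hi, lo))         # interleave hi/lo per sample
  dim(samp) <- NULL
  scan <- matrix(samp, nrow = 2L * w)      # one column per image row
  raw_rows <- rbind(as.raw(rep(0L, h)), matrix(scan, nrow = 2L * w))
  idat <- memCompress(as.raw(as.vector(raw_rows)), type = "gzip")  # zlib stream
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(.png_chunk("IHDR", ihdr), con)
  writeBin(.png_chunk("IDAT", idat), con)
  writeBin(.png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit (or 8-bit) grayscale PNG as digital numbers
#'
#' @param path PNG file path.
#' @return Integer-valued numeric matrix on the stored scale (16-bit
#'   files give values in [0, 65535]).
#' @export
read_png16 <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    ir_stop(sprintf("'%s' is not a single-channel grayscale image", path),
            "ir_format_error")
  round(img * 65535)
}

#' Write a 32-bit float TIFF
#'
#' Stores a numeric matrix (e.g., temperatures in degrees C) as an
#' uncompressed single-strip little-endian TIFF with IEEE float samples.
#' `NaN` values are stored as such. `tiff::readTIFF(path)` reads it back.
#'
#' @param mat Numeric matrix; `mat[row, col]` is the pixel at image row
#'   `row`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_float <- function(mat, path) {
  if (!is.matrix(mat) || !is.numeric(mat))
    ir_stop("float TIFF requires a numeric matrix", "ir_format_error")
  h <- nrow(mat); w <- ncol(mat)
  n_tags <- 9L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_tags * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)   # little-endian magic
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(c(id)), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  writeBin(as.integer(n_tags), con, size = 2L, endian = "little")
  tag(256L, 3L, 1L, w)            # ImageWidth
  tag(257L, 3L, 1L, h)            # ImageLength
  tag(258L, 3L, 1L, 32L)          # BitsPerSample
  tag(259L, 3L, 1L, 1L)           # Compression: none
  tag(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_off)     # StripOffsets
  tag(277L, 3L, 1L, 1L)           # SamplesPerPixel
  tag(279L, 4L, 1L, 4L * w * h)   # StripByteCounts
  tag(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4L, endian = "little")  # next IFD: none
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 32-bit float TIFF written by [write_tiff_float()]
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_tiff_float <- function(path) {
  m <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(m)) == 3L && dim(m)[3] == 1L) m <- m[, , 1L]
  m
}

# 16-bit byte swap: exchanges high and low bytes of each sample.
swap16 <- function(v) (v %% 256) * 256 + v %/% 256
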