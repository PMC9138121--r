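# Rendering: histogram-stretched ranges, LUT application and decoding,
# scale bars and video export.

test_that("tail exclusion matches the stated fractions on a uniform histogram", {
  vals <- seq(10, 40, length.out = 1000)  # 1000 distinct, evenly spread
  outside <- function(rng) sum(vals < rng$t_min | vals > rng$t_max)
  expect_identical(outside(compute_display_range(vals, "low")), 0L)
  expect_identical(outside(compute_display_range(vals, "normal")), 3L)
  expect_identical(outside(compute_display_range(vals, "high")), 30L)
  # low contrast is the exact data range
  rng <- compute_display_range(vals, "low")
  expect_identical(c(rng$t_min, rng$t_max), range(vals))
})

test_that("degenerate and undefined inputs are handled", {
  expect_warning(rng <- compute_display_range(rep(25, 50), "normal"),
                 class = "ir_degenerate_range")
  expect_equal(c(rng$t_min, rng$t_max), c(24.5, 25.5))
  expect_error(compute_display_range(c(NaN, NaN, 20), "low"),
               class = "ir_parameter_error")
  # NaN pixels are ignored, not counted in the tails
  v <- c(seq(0, 10, length.out = 100), rep(NaN, 50))
  rng2 <- compute_display_range(v, "low")
  expect_equal(c(rng2$t_min, rng2$t_max), c(0, 10))
})

test_that("global scope shares one range across a set, per-image does not", {
  frames <- list(a = matrix(seq(10, 20, length.out = 24), 4, 6),
                 b = matrix(seq(30, 40, length.out = 24), 4, 6))
  g <- display_ranges(frames, "low", "global")
  expect_identical(g[[1]], g[[2]])
  expect_equal(c(g[[1]]$t_min, g[[1]]$t_max), c(10, 40))
  p <- display_ranges(frames, "low", "per-image")
  expect_equal(c(p[[1]]$t_min, p[[1]]$t_max), c(10, 20))
  expect_equal(c(p[[2]]$t_min, p[[2]]$t_max), c(30, 40))
  # a shared temperature renders identically under global scope
  rgb_a <- apply_palette(frames$a, g[[1]])
  rgb_b <- apply_palette(frames$b, g[[2]])
  expect_identical(rgb_a[1, 1, ], apply_palette(matrix(frames$a[1, 1]),
                                                g[[2]])[1, 1, ])
  expect_false(identical(rgb_a, rgb_b))
})

test_that("palette endpoints, midpoint tie-break and undefined pixels map as documented", {
  rng <- structure(list(t_min = 20, t_max = 30, contrast = "low"),
                   class = "display_range")
  lut <- palette_lut("inferno")
  frame <- matrix(c(20, 30, 25, 19, 31, NaN), 2, 3)
  expect_message(rgb <- apply_palette(frame, rng), "undefined")
  expect_equal(rgb[1, 1, ] * 255, unname(lut[1, ]))     # t_min -> first color
  expect_equal(rgb[2, 1, ] * 255, unname(lut[256, ]))   # t_max -> last color
  expect_equal(rgb[1, 2, ] * 255, unname(lut[129, ]))   # midpoint -> upper bin (index 128)
  expect_equal(rgb[2, 2, ], rgb[1, 1, ])                # below range clamps
  expect_equal(rgb[1, 3, ], rgb[2, 1, ])                # above range clamps
  expect_equal(rgb[2, 3, ], rgb[1, 1, ])                # NaN -> palette minimum
  # greyscale: cold black, warm white
  grey <- apply_palette(matrix(c(20, 30), 1), rng, "greyscale")
  expect_equal(grey[1, 1, ], c(0, 0, 0))
  expect_equal(grey[1, 2, ], c(1, 1, 1))
})

test_that("rendered images decode back within one LUT bin width", {
  set.seed(33)
  frame <- matrix(runif(40 * 30, 15, 45), 30, 40)
  for (pal in c("inferno", "greyscale")) {
    rng <- compute_display_range(frame, "normal")
    rgb <- apply_palette(frame, rng, pal)
    dec <- decode_rendered(rgb, rng, pal)
    inr <- frame >= rng$t_min & frame <= rng$t_max
    expect_true(all(abs(dec[inr] - frame[inr]) <=
                      (rng$t_max - rng$t_min) / 255))
  }
})

test_that("both palettes have monotonically non-decreasing luma", {
  for (pal in c("inferno", "greyscale")) {
    lut <- palette_lut(pal)
    luma <- 0.299 * lut[, 1] + 0.587 * lut[, 2] + 0.114 * lut[, 3]
    expect_true(all(diff(luma) >= 0))
  }
})

test_that("the scale bar is local, oriented warm-up and labelled", {
  rng <- structure(list(t_min = 18.25, t_max = 41.75, contrast = "low"),
                   class = "display_range")
  frame <- matrix(seq(18.25, 41.75, length.out = 80 * 60), 60, 80)
  rgb <- apply_palette(frame, rng)
  out <- add_scale_bar(rgb, rng, size = "small")
  lut <- palette_lut("inferno") / 255
  # untouched outside the bar+label region (left half certainly untouched)
  expect_identical(out[, 1:40, ], rgb[, 1:40, ])
  # bar columns: warmest color on top, coldest at the bottom
  bar_cols <- (80 - 2 - 6 + 1):(80 - 2)
  bar_rows <- which(apply(out[, bar_cols[1], , drop = FALSE] !=
                            rgb[, bar_cols[1], , drop = FALSE], 1, any))
  expect_equal(unname(out[min(bar_rows), bar_cols[1], ]), unname(lut[256, ]))
  expect_equal(unname(out[max(bar_rows), bar_cols[1], ]), unname(lut[1, ]))
  # labels changed some pixels above and below the bar
  expect_false(identical(out[1:7, , ], rgb[1:7, , ]))
  expect_error(add_scale_bar(apply_palette(matrix(c(20, 30), 1), rng), rng),
               class = "ir_render_error")
  expect_error(add_scale_bar(rgb[1:30, 1:20, , drop = FALSE], rng,
                             size = "large"),
               "small", class = "ir_render_error")
})

test_that("video export writes one container frame per input frame", {
  frame <- matrix(seq(10, 30, length.out = 24 * 32), 24, 32)
  rng <- compute_display_range(frame, "low")
  rgb <- apply_palette(frame, rng)
  frames <- list(rgb, rgb * 0.5, rgb * 0.25)
  path <- tempfile(fileext = ".avi")
  export_video(frames, path, fps = 10)
  info <- irproc:::read_avi_info(path)
  expect_equal(info$frames, 3)
  expect_equal(info$width, 32)
  expect_equal(info$height, 24)
  expect_equal(info$fps, 10)
  # single frame is a valid video
  export_video(frames[1], path)
  expect_equal(irproc:::read_avi_info(path)$frames, 1)
  expect_error(export_video(list(rgb, rgb[1:10, , , drop = FALSE]), path),
               class = "ir_render_error")
  expect_error(export_video(list(), path), class = "ir_render_error")
})
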