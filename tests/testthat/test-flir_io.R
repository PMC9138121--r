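# I/O layer: raster writers, sidecar metadata, byte-order resolution,
# parameter tables and temperature CSV grids.

test_that("16-bit PNG writer round-trips digital numbers exactly", {
  set.seed(42)
  dn <- matrix(sample(0:65535, 35 * 21, replace = TRUE), 21, 35)
  path <- tempfile(fileext = ".png")
  write_png16(dn, path)
  expect_identical(read_png16(path), dn + 0)  # numeric comparison
  expect_error(write_png16(matrix(-1, 2, 2), tempfile()),
               class = "ir_format_error")
  expect_error(write_png16(matrix(0.5, 2, 2), tempfile()),
               class = "ir_format_error")
})

test_that("float TIFF writer stores temperatures including NaN", {
  m <- matrix(c(-70.25, 20.5, 39.99, NaN, 0, 100), 2, 3)
  path <- tempfile(fileext = ".tif")
  write_tiff_float(m, path)
  r <- read_tiff_float(path)
  expect_equal(dim(r), dim(m))
  expect_true(is.nan(r[2, 2]))
  expect_equal(r[!is.na(m)], m[!is.na(m)], tolerance = 1e-6)
})

test_that("byte-order resolution is a pure table over container and model", {
  ex <- c("SYNTH-SWAP-A", "SYNTH-SWAP-B")
  cases <- list(
    list("PNG",  "SYNTH-T1",     "little"),
    list("PNG",  "SYNTH-SWAP-A", "big"),
    list("TIFF", "SYNTH-T1",     "big"),
    list("TIFF", "SYNTH-SWAP-B", "little"),
    list("png",  "anything",     "little"))
  for (cs in cases)
    expect_identical(resolve_byte_order(cs[[1]], cs[[2]], ex), cs[[3]])
  expect_error(resolve_byte_order("JPEG", "m", ex), class = "ir_format_error")
  # bundled exception config is non-empty and drives the default
  expect_true(length(byte_order_exceptions()) >= 3)
  expect_identical(resolve_byte_order("PNG", byte_order_exceptions()[1]),
                   "big")
})

test_that("wrong byte order yields byte-swapped values", {
  spec <- two_region_spec()
  sc <- render_scene(spec)
  dir <- tempfile(); fx <- package_fixture(sc$raw, spec, dir, "swapt")
  right <- extract_raw_frame(fx$payload, "little")  # PNG payload, no exception
  wrong <- extract_raw_frame(fx$payload, "big")
  expect_identical(right, sc$raw + 0)
  expect_identical(wrong, (sc$raw %% 256) * 256 + sc$raw %/% 256)
})

test_that("sidecar metadata extraction is lossless and read-only", {
  params <- acquisition_params(0.87, 23.5, 0.61, 19.5, 2.5)
  spec <- two_region_spec(params = params, camera_model = "SYNTH-XL9",
                          image_type = "TIFF")
  sc <- render_scene(spec)
  dir <- tempfile(); fx <- package_fixture(sc$raw, spec, dir, "meta")
  sum_before <- tools::md5sum(c(fx$payload, fx$params))
  meta <- extract_metadata(fx$payload)
  expect_identical(tools::md5sum(c(fx$payload, fx$params)), sum_before)
  expect_identical(meta$camera_model, "SYNTH-XL9")
  expect_identical(meta$raw_image_type, "TIFF")
  expect_equal(meta$cal, spec$cal)
  expect_equal(meta$atm, spec$atm)
  expect_equal(meta$user, params)
  # second extraction gives the identical object (idempotence)
  expect_equal(extract_metadata(fx$payload), meta)
})

test_that("non-radiometric input is rejected with a format error", {
  plain <- tempfile(fileext = ".png")  # no sidecar CSV next to it
  png::writePNG(matrix(0.5, 4, 4), plain)
  expect_error(extract_metadata(plain), class = "ir_format_error")
  expect_error(extract_metadata(tempfile(fileext = ".jpg")),
               class = "ir_format_error")
})

test_that("parameter tables round-trip losslessly and validate their schema", {
  specs <- lapply(1:3, function(i)
    two_region_spec(params = acquisition_params(0.9 + i / 100, 20 + i,
                                                0.4 + i / 10, 19, i)))
  recs <- do.call(rbind, lapply(seq_along(specs), function(i) {
    meta <- structure(list(camera_model = "SYNTH-T1", raw_image_type = "PNG",
                           cal = specs[[i]]$cal, atm = specs[[i]]$atm,
                           user = specs[[i]]$params),
                      class = "image_metadata")
    irproc:::.record_from_metadata(meta, sprintf("img%03d.png", i))
  }))
  path <- tempfile(fileext = ".csv")
  write_parameter_table(recs, path)
  back <- read_parameter_table(path)
  expect_equal(back, recs)

  # humidity is stored in percent and normalized to a fraction at ingest
  expect_equal(back$airRelHumidity_perc[1], 50)
  meta <- irproc:::.metadata_from_record(as.list(back[1, ]), "x")
  expect_equal(meta$user$rel_humidity, 0.5)

  # unknown columns survive the round trip
  recs2 <- recs; recs2$note <- c("a", "b", "c")
  write_parameter_table(recs2, path)
  expect_equal(read_parameter_table(path)$note, c("a", "b", "c"))

  # schema violations are named
  broken <- recs[, setdiff(names(recs), "objEmissivity")]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_parameter_table(p2), "objEmissivity",
               class = "ir_schema_error")
  recs3 <- recs; recs3$sensorG <- c("21106.77", "oops", "1")
  utils::write.csv(recs3, p2, row.names = FALSE)
  expect_error(read_parameter_table(p2), "row 2.*sensorG",
               class = "ir_schema_error")
})

test_that("temperature CSV grids round-trip with the NaN sentinel", {
  m <- matrix(c(20.125, -70.004, NaN, 39.995), 2, 2)
  path <- tempfile(fileext = ".csv")
  write_temperature_csv(m, path)
  txt <- readLines(path)
  expect_length(txt, 2)
  expect_match(txt[1], "NaN")
  back <- read_temperature_csv(path)
  expect_true(is.nan(back[1, 2]))
  expect_equal(back[!is.na(m)], round(m[!is.na(m)], 2))

  writeLines(c("1,2,3", "4,5"), path)
  expect_error(read_temperature_csv(path), class = "ir_format_error")
  file.create(path2 <- tempfile(fileext = ".csv"))
  expect_error(read_temperature_csv(path2), class = "ir_format_error")
})
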