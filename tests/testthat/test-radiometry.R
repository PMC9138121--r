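# Radiometric core: calibration model, signal decomposition,
# transmissivity and the raw-to-temperature inversion.

test_that("temperature unit conversion enforces absolute zero", {
  expect_equal(celsius_to_kelvin(0), 273.15)
  expect_equal(celsius_to_kelvin(25), 298.15)
  expect_equal(kelvin_to_celsius(celsius_to_kelvin(-70)), -70)
  expect_error(celsius_to_kelvin(-273.15), class = "ir_invalid_temperature")
  expect_error(kelvin_to_celsius(0), class = "ir_invalid_temperature")
})

test_that("air water content matches direct evaluation of the polynomial", {
  # frozen from an independent evaluation of the printed polynomial
  expect_equal(air_water_content(20, 0.5), 8.563981576394681, tolerance = 1e-12)
  expect_equal(air_water_content(30, 1.0), 30.22105448955349, tolerance = 1e-12)
  expect_equal(air_water_content(0, 0.3), 1.4257916390943512, tolerance = 1e-12)
  expect_equal(air_water_content(-10, 0.8), 1.8462487885323886, tolerance = 1e-12)
  # multiplicative zero at any temperature
  for (t in c(-20, 0, 17.3, 45)) expect_identical(air_water_content(t, 0), 0)
  expect_error(air_water_content(20, 1.2), class = "ir_parameter_error")
})

test_that("transmissivity is exactly 1 at zero distance and decreases with d and H", {
  atm <- default_atmosphere()
  for (H in c(0, 3.2, 8.56, 30))
    expect_identical(atmospheric_transmissivity(0, H, atm), 1)
  H <- air_water_content(20, 0.5)
  tau4 <- atmospheric_transmissivity(4, H, atm)
  expect_true(tau4 > 0 && tau4 < 1)
  # strictly decreasing in distance
  taus <- vapply(c(0, 0.5, 1, 2, 5, 10, 25),
                 atmospheric_transmissivity, numeric(1), H = H, atm = atm)
  expect_true(all(diff(taus) < 0))
  # strictly decreasing in water content at fixed distance
  taus_h <- vapply(c(0.5, 2, 8, 20, 40), function(h)
    atmospheric_transmissivity(4, h, atm), numeric(1))
  expect_true(all(diff(taus_h) < 0))
  # single-exponential model with positive coefficients, same property
  simple <- atmosphere_model(0.01, 0.02, 0.004, 0.006, 0.5)
  taus_s <- vapply(c(0, 1, 4, 9), atmospheric_transmissivity, numeric(1),
                   H = 10, atm = simple)
  expect_true(all(diff(taus_s) < 0))
})

test_that("transmissivity clamping warns and bounds the result", {
  # X > 1 amplifies a growing term at extreme water content / distance
  atm <- atmosphere_model(-0.05, 0.01, -0.01, -0.001, 1.9)
  expect_warning(tau <- atmospheric_transmissivity(100, 50, atm),
                 class = "ir_tau_clamped")
  expect_true(tau <= 1)
})

test_that("component signal follows the calibration law", {
  cal <- scalar_cal()
  # zero weight leaves only the offset
  expect_identical(component_signal(300, 0, cal), cal$O)
  expect_identical(component_signal(300, 0, cal, include_offset = FALSE), 0)
  # frozen from an independent evaluation of the calibration law
  expect_equal(component_signal(300, 0.95, cal), 3545.3993246043938,
               tolerance = 1e-12)
  # diverges as T grows without bound (denominator -> 0+ for F = 1)
  expect_true(component_signal(1e7, 1, cal) >
                component_signal(1e3, 1, cal))
  expect_true(component_signal(1e9, 1, cal) > 1e10)
  expect_error(component_signal(-10, 0.5, cal),
               class = "ir_invalid_temperature")
})

test_that("object signal inverts the three-source composition algebraically", {
  # identity case
  expect_equal(object_signal(12345, 1, 0, 0), 12345)
  # composing S = tau*a + tau*b + c recovers exactly a
  a <- 9500; b <- 480; cc <- 70; tau <- 0.93
  expect_equal(object_signal(tau * a + tau * b + cc, tau, b, cc), a,
               tolerance = 1e-12)
  # hand arithmetic oracle
  expect_equal(object_signal(15000, 0.95, 14000, 13000),
               15000 / 0.95 - 14000 - 13000 / 0.95, tolerance = 1e-12)
  expect_error(object_signal(100, 0, 0, 0), class = "ir_parameter_error")
})

test_that("temperature inversion is the exact inverse of the forward law", {
  for (cal in list(scalar_cal(), default_calibration(),
                   calibration_constants(G = 15000, O = -5000, B = 1400,
                                         R = 0.01, F = 0.9))) {
    for (T in seq(233.15, 373.15, by = 10)) {
      for (e in c(0.5, 0.95, 1)) {
        S <- component_signal(T, e, cal)
        expect_equal(object_temperature(S, e, cal), T, tolerance = 1e-9)
      }
    }
  }
})

test_that("inversion hits B exactly at the forced signal and errors at the offset", {
  cal <- scalar_cal()
  S_obj <- cal$O + cal$G * 0.95 / (cal$R * (exp(1) - cal$F))
  expect_equal(object_temperature(S_obj, 0.95, cal), cal$B, tolerance = 1e-9)
  expect_error(object_temperature(cal$O, 0.95, cal),
               class = "ir_signal_domain_error")
})

test_that("object temperature is strictly increasing in the object signal", {
  cal <- default_calibration()
  S <- seq(cal$O + 10, cal$O + 30000, length.out = 200)
  T <- object_temperature(S, 0.95, cal)
  expect_true(all(diff(T) > 0))
})

test_that("frame inversion recovers a uniform 300 K scene", {
  spec <- scene_spec(24, 16, background_C = 26.85, quantize = TRUE)
  sc <- render_scene(spec)
  temp <- frame_to_temperature(sc$raw, spec$params, spec$cal, spec$atm)
  expect_equal(dim(temp), dim(sc$raw))
  expect_true(all(abs(temp - 26.85) < 0.05))
})

test_that("frame inversion recovers a two-region scene within quantization", {
  spec <- two_region_spec()
  sc <- render_scene(spec)
  temp <- frame_to_temperature(sc$raw, spec$params, spec$cal, spec$atm)
  expect_lt(abs(mean(temp[sc$truth == 20]) - 20), 0.05)
  expect_lt(abs(mean(temp[sc$truth == 40]) - 40), 0.05)
  # DN ordering is preserved among valid pixels
  o <- order(as.vector(sc$raw))
  expect_true(all(diff(as.vector(temp)[o]) >= 0))
})

test_that("out-of-domain pixels become NaN without aborting the frame", {
  spec <- two_region_spec()
  sc <- render_scene(spec)
  raw <- sc$raw
  raw[3, 5] <- 0  # signal far below the composed offset
  expect_message(temp <- frame_to_temperature(raw, spec$params, spec$cal,
                                              spec$atm),
                 "undefined")
  expect_true(is.nan(temp[3, 5]))
  expect_identical(attr(temp, "undefined_pixels"), 1L)
  expect_false(anyNA(temp[-((5 - 1) * nrow(temp) + 3)]))
})

test_that("inferred temperature is non-increasing in assumed emissivity", {
  spec <- two_region_spec()  # 40 C object over a 20 C reflected background
  sc <- render_scene(spec)
  means <- vapply(c(0.85, 0.9, 0.95, 1), function(e) {
    p <- acquisition_params(e, 20, 0.5, 20, 1)
    mean(frame_to_temperature(sc$raw, p, spec$cal, spec$atm)[sc$truth == 40])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("no output floor: a -70 C scene is recovered below -40 C", {
  spec <- scene_spec(24, 16, background_C = -70, quantize = TRUE)
  sc <- render_scene(spec)
  temp <- frame_to_temperature(sc$raw, spec$params, spec$cal, spec$atm)
  expect_true(all(temp < -40))
  expect_true(all(abs(temp + 70) < 0.05))
})
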