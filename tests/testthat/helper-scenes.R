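# Shared fixture builders. Scalar-model tests use a calibration set with
# a large negative offset (as real cameras store); frame-level tests use
# the package defaults, whose positive offset keeps composed signals
# inside the 16-bit range.

scalar_cal <- function() {
  calibration_constants(G = 21106.77, O = -7261, B = 1501, R = 0.012545, F = 1)
}

two_region_spec <- function(seed = 1L, quantize = TRUE, noise_sd = 0,
                            camera_model = "SYNTH-T1", image_type = "PNG",
                            params = acquisition_params(0.95, 20, 0.5, 20, 1)) {
  scene_spec(48, 36, background_C = 20,
             objects = list(scene_object("rectangle", x = 12, y = 18,
                                         width = 16, height = 20, temp_C = 40)),
             params = params, seed = seed, quantize = quantize,
             noise_sd = noise_sd, camera_model = camera_model,
             image_type = image_type)
}

render_scene <- function(spec) {
  sc <- generate_scene(spec)
  raw <- forward_signal(sc$truth, sc$emissivity, spec)
  list(truth = sc$truth, emissivity = sc$emissivity, raw = raw)
}

make_fixture_folder <- function(n = 3, dir = tempfile(),
                                quantize = TRUE, seeds = seq_len(n)) {
  specs <- lapply(seq_len(n), function(i)
    scene_spec(48, 36, background_C = 18 + i,
               objects = list(scene_object("disk", x = 16, y = 18, radius = 7,
                                           temp_C = 35 + i)),
               seed = seeds[i], quantize = quantize))
  fx <- simulate_folder(specs, dir)
  list(dir = dir, specs = specs, fixtures = fx)
}
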