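Package: irproc
Title: Radiometric Processing of Infrared Thermal Camera Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw sensor signals from radiometric thermal-camera
    images into calibrated object temperatures using an open, fully
    documented physics chain: a Planck-type sensor calibration model, a
    three-source decomposition of the measured signal (object, reflected
    surroundings, atmosphere) and a water-content based atmospheric
    transmissivity model. Provides reproducible batch processing of image
    folders with per-image, global or file-based parameterization,
    mask-based per-object temperature statistics, quantitatively accurate
    false-color rendering (perceptually uniform palette, histogram
    stretching, scale bars, video export) and pixelwise comparison against
    reference temperature exports. Includes a synthetic scene generator
    implementing the forward radiometric model for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
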