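Package: fibercube
Title: Fiber-Bundle Integral-Field Raman Imaging at Desk Scale
Version: 0.1.0
Authors@R:
    person("fibercube", "developers", email = "fibercube@example.org",
           role = c("aut", "cre"))
Description: Toolkit for single-exposure Raman chemical imaging with a
    fiber-bundle integral-field spectrograph. Simulates raw CCD frames
    (bias, flat, arc, science) from a 20x20 fiber probe head feeding a
    pseudo-slit, reduces them to row-stacked spectra (master bias, trace
    finding, throughput flat, arc wavelength calibration, aperture
    extraction, cosmic-ray cleaning), assembles a spatial-spectral data
    cube on a common Raman-shift axis, and produces chemical maps via
    iterative modified-polyfit fluorescence baseline removal, reference
    normalization, and Gaussian peak fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
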