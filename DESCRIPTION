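Package: fpmtools
Title: Parallel Fourier Ptychography for Multi-Well Plate Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for parallel Fourier ptychographic microscopy
    (FPM) of 96-well plates: LED-array illumination geometry and multi-well
    scheduling, Snell's-law calibration of illumination angles through a liquid
    meniscus, embedded pupil function recovery (EPRY) phase retrieval with
    adaptive step size, blind two-stage computational refocusing, Zernike
    wavefront analysis, digital frame averaging with static-pattern removal,
    and feather-blend tile stitching. A coherent forward simulator (phase
    targets, microbead fields, sensor noise) lets the full pipeline run and be
    validated without any instrument.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
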