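Package: actithigh
Title: Movement Behaviour Classification from Thigh-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies movement behaviours (sedentary, standing, moving,
    walking, running, stair climbing, cycling) from thigh-worn triaxial
    accelerometer recordings using an Acti4-lineage decision tree over
    windowed movement-intensity and orientation features, at configurable
    sampling frequencies. Includes device autocalibration and individual
    orientation calibration, multi-device clock synchronisation via
    heel-drop anchors and cross-correlation drift correction, a
    second-order polynomial correction for dynamic-range saturation of the
    standard-deviation feature, a synthetic thigh-signal simulator for all
    behaviours, and a validation toolkit: annotation alignment, confusion
    matrices, one-versus-all classification metrics, Cohen's kappa, and
    Bland-Altman agreement analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
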