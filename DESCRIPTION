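Package: lithocav
Title: Focused-Ultrasound Fields, Cavitation Regions and Model-Stone
    Surface Damage Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for laboratory-scale high-intensity focused ultrasound
    (HIFU) lithotripsy studies. Computes the linear acoustic field of a
    spherical-bowl transducer (O'Neil on-axis solution and off-axis
    Rayleigh surface integral), runs a time-domain axisymmetric linear
    acoustic solver with power-law absorption and a stone impedance jump,
    extracts supra-threshold cavitation regions and their spherical-cap
    damage coefficients, predicts the optimum source-to-stone distance,
    and analyses shadowgraph image stacks (minimum intensity projection,
    bubble census, cloud tracking, stone-surface intensity profiles).
    A synthetic shadowgraph scene generator with full ground truth
    supports closed-loop recovery testing of every image-analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
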