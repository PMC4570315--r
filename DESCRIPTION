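Package: vinotaste
Title: Colorimetric Taste-Sensor Arrays for White Wine Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dye-bead colorimetric
    sensor arrays used to quantify white wine taste. Generates wine-like
    taste-chemical panels and rendered sensor-array image pairs with known
    ground truth, extracts 24 RGB-difference colour features from well
    images, computes weighted sweetness, molar sourness and tannin-based
    astringency scores, characterises samples by principal component
    analysis, and trains feed-forward neural network regressors with
    incremental, batch, RPROP and QuickPROP back-propagation, selected by
    coefficient of determination and root mean square error of prediction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
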