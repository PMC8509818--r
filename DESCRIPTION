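Package: spiralscreen
Title: Spiral-Drawing Screening for Carpal Tunnel Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening carpal tunnel syndrome from stylus
    spiral-drawing recordings captured on a pressure-sensitive tablet.
    Implements the Archimedean guide spiral and its polar-coordinate
    tracing error (RMSE), jerk computation from stylus trajectory and
    pressure with chunked Hanning-window FFT spectral features, maximum
    pen-pressure extraction, and a support-vector-machine screening
    classifier evaluated by leave-one-out cross-validation and ROC
    analysis, including the full grid of feature-set combinations. A
    synthetic cohort simulator generates labelled stylus recordings with
    group-dependent tremor, shape error and pen pressure so the whole
    pipeline can be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
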