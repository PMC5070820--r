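Package: accelcal
Title: Accelerometer Cut-Point Calibration and Cross-Validation Against
    Direct Observation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates physical-activity intensity cut points for
    hip-worn accelerometer activity counts against a momentary
    time-sampled direct-observation criterion (SOFIT student-activity
    codes), and cross-validates them in a held-out participant group.
    Implements epoch reintegration (10-s to 20-s), time alignment of
    count and observation streams, receiver operating characteristic
    analysis with Youden-index threshold selection and Hanley-McNeil
    confidence intervals, hierarchical sedentary/moderate/vigorous
    cut-point assembly for the vertical axis and vector magnitude, and
    classification-agreement statistics (sensitivity, specificity,
    total agreement, Cohen's kappa).  A synthetic-session generator
    with an analytic threshold oracle supports end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
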