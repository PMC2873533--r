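Package: sodpcr
Title: Shape-Based Kinetic Outlier Detection for Real-Time PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for real-time quantitative PCR amplification
    curves. Each run is parameterized by nonlinear least-squares fitting of a
    five-parameter Richards growth function; the fitted plateau, the
    y-coordinate of the inflection point and the tangent slope at the
    inflection point form a concentration-independent shape fingerprint.
    Runs whose fingerprint lies at a squared Mahalanobis distance from the
    standard-curve reference set exceeding the chi-squared (3 df) critical
    value are flagged as kinetic outliers (SOD). Also provides the
    efficiency-based comparator (KOD) via window-of-linearity log-linear
    regression, fit-point threshold-cycle quantification with standard-curve
    calibration, confusion-matrix evaluation against quantification-error
    truth labels, and a synthetic dilution-series and inhibition simulator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
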