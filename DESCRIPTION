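Package: rrfquant
Title: Targeted LC-MS Metabolite Quantification by Relative Response Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An engine for absolute quantification in targeted LC-MS
    metabolomics. Fits weighted (1/x) external calibration curves with a
    back-calculation bias filter and R-squared gate, estimates limits of
    detection and quantification by line extrapolation against blank noise,
    selects low-variance stable-isotope-labeled internal standards as
    reference compounds, computes response factors and relative response
    factors (RRF), and quantifies samples both by external calibration and
    by single-point RRF calibration. Includes matrix-effect (ion
    suppression) evaluation, AutoQC-style system-suitability metrics, and a
    synthetic LC-MS response simulator with known ground truth (ionization
    efficiency, detector saturation, matrix suppression, multiplicative
    replicate noise) so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
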