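Package: iitqa
Title: Panoramic Quality Assessment for Investigator-Initiated Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores investigator-initiated trials (IITs) on a 13-index,
    4-attribute quality instrument (progress, quality, regulation,
    scientificity), validates the instrument structure with a built-in
    second-order confirmatory factor analysis engine (maximum likelihood
    estimation with CMIN/DF, GFI, CFI, TLI, RMSEA and SRMR fit indices),
    simulates synthetic IIT cohorts from the second-order factor model for
    testing and calibration, and reports cohorts via summary tables and
    radar charts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
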