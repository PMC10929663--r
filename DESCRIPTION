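Package: occuadjust
Title: Adjustment Estimators for Mean Occupancy from Nonprobability Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Descriptive inference for the mean of a binary variable (species
    occupancy across areal grid units) from large, unrepresentative
    nonprobability samples such as opportunistic citizen-science records.
    Implements the naive and design-based estimators plus six adjustment
    estimators (quasirandomization, poststratification, superpopulation
    modelling, a doubly robust estimator, stratified subsampling, and
    multilevel regression and poststratification), representativeness
    diagnostics based on the data defect correlation and binned
    auxiliary-distribution comparisons, bootstrap and analytic 95 percent
    intervals, two-period trend estimation, and a synthetic-landscape
    generator with known ground truth for estimator validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    ranger,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
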