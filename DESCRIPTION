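Package: spectraits
Title: Segment-Scale Estimation of Plant Biochemical Traits from
    Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for estimating dry matter, water, nitrogen and
    chlorophyll content of chopped plant segments from 350-2500 nm
    reflectance spectra measured in a dark chamber, and for scaling the
    estimates to whole plants.  Provides white-reference calibration and
    wide-CSV spectra input/output, an exact Gaussian-process regression
    engine with marginal-likelihood hyperparameter optimisation, direct,
    indirect (water-content mass balance) and inverse-RMSE ensemble dry
    matter estimators, residual-rate quality control and plant-scale
    aggregation, leave-one-treatment-out cross-validation, vertical
    biochemical profile interpolation with correlation and ANOVA
    analysis, and a seeded virtual-instrument simulator that generates
    complete synthetic datasets for testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
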