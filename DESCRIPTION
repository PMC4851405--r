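Package: phenolag
Title: Lagged Soil-Moisture and Day-Length Modelling of Savannah Leaf Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling savannah leaf phenology from lagged climate
    drivers. Provides a stochastic site generator (pulsed soil moisture,
    solar day length, lagged log-linear NDVI response sampled as 16-day
    composites), preprocessing of NDVI and climate series onto a common
    8-day grid (linear gap-filling, adaptive Savitzky-Golay smoothing,
    median/maximum window aggregation, collinearity screening), exhaustive
    BIC selection over lagged and transformed regression candidates,
    relative-importance decomposition of r-squared by averaging over
    regressor orderings, site-holdout cross-validation with RMSE, r-squared
    and variance inflation factors, and start-of-season and amplitude
    phenometrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
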