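Package: nitroplan
Title: Seasonal-Spatial Optimization of Cropland and Nitrogen Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated economic-ecological modelling of crop production and
    nitrogen runoff at district scale. Provides a seeded synthetic-data
    generator for district-by-season land-use panels, household yield samples
    and toy elevation/load rasters; a light-weight nutrient-delivery-ratio
    stage that routes nitrogen loads down a D8 flow field with per-cell
    retention and isolates the fertilizer-attributable delivery ratio by
    two-run differencing; a seemingly-unrelated-regression estimator for a
    logistic system of seasonal crop-share equations with analytic price
    marginal effects; inverse-hyperbolic-sine estimation of Cobb-Douglas
    yield-nitrogen elasticities with district fixed effects and per-district
    productivity calibration; and nonlinear programs that minimize national
    nitrogen export subject to revenue, food-security and cropland
    constraints under seasonal, seasonal-spatial and price-instrument
    (integrated) scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    nloptr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
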