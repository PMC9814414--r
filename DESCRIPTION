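Package: phenocap
Title: Capped Thermal-Time Models for Tundra Flowering Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects maximum-temperature limits on flowering phenology from
    hourly canopy-temperature records and repeated flower censuses. Computes
    growing-degree-day forcing with an optional maximum temperature cap
    (GDD_max), derives seasonal new-flower count series from census tables,
    fits penalized-spline Poisson models of the seasonal flowering curve
    with an intercensus-interval offset and year random intercepts, scans a
    grid of candidate temperature caps by AIC to estimate the threshold,
    quantifies uncertainty with a leave-one-year-out jackknife, and compares
    the predictive skill of day-of-year, GDD and capped-GDD models on
    ambient and experimentally warmed plots. Includes a synthetic-data
    generator with known ground truth (seasonal hourly temperatures,
    passive-warming treatment effects, snowmelt dates, plot-level flower
    censuses) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
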