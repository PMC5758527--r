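Package: musselclim
Title: Shell Convexity, Temperature Calibration and Climatic Suitability
    Modelling for Freshwater Pearl Mussels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking freshwater pearl mussel
    (Margaritifera margaritifera) shell convexity to summer air
    temperature at continental scale. Provides shell morphometric
    indices and population-level statistics (filtering, aggregation,
    Lilliefors normality checks, pooled t-tests, ANCOVA-style general
    linear models with Type III sums of squares, separate-slopes
    tests), extraction of candidate climatic predictors from gridded
    monthly air temperature (windowed mean summer temperature,
    seasonal and annual means, effective temperature sums, thermal
    growing season length), linear calibration regressions with
    k-fold cross-validation (MAPE, Tofallis log accuracy ratio,
    min-max accuracy) and Moran's I spatial autocorrelation
    diagnostics, von Bertalanffy growth estimation via the
    Ford-Walford method, derivation of viable/declining/unsuitable
    shell-convexity thresholds, gridded projection and classification
    of climatically suitable areas under past and future climates,
    and a fully seeded synthetic-data generator so every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
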