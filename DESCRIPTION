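Package: plantargait
Title: Plantar-Pressure Gait Features and Functional-Test Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for wearable plantar-pressure insole
    recordings (8 sensors per foot, 20 Hz): gait-cycle segmentation from
    the total vertical ground reaction force, extraction of a 380-gait-
    feature plus 4-physical-characteristic database (peak plantar
    pressure, pressure gradients, temporal features, pressure-time
    integrals, center-of-pressure trajectory statistics, symmetry
    indices, cycle-to-cycle variability, and weak-foot features),
    stepwise feature selection (Spearman filter, minimum-redundancy
    maximum-relevance, sequential floating wrapper search), and
    individual, stacked, and relative-index-weighted ensemble regressors
    that predict 40-m fast-paced walk test and timed up-and-go test
    completion times. Includes a synthetic bimodal-stance gait generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    rpart,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
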