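Package: rangerisk
Title: Ensemble Species Distribution Models and Projected Extinction Risk
    for Range-Restricted Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing climate-change extinction risk of
    narrow-range species from occurrence records and gridded climate
    predictors. Fits a TSS-weighted ensemble of four habitat-suitability
    learners (GLM, GAM, random forest, boosted regression trees),
    binarizes suitability surfaces with minimum-training-presence,
    maximum-sensitivity-plus-specificity and fixed thresholds, computes
    alpha-hull extent of occurrence and grid-cell area of occupancy under
    full- and no-dispersal scenarios, and maps projected occupancy loss to
    IUCN-style risk categories. Includes a virtual-species simulator
    (spatially autocorrelated predictor surfaces, parametric niches,
    presence-only sampling, additive climate deltas, categorical land
    cover) so the whole workflow can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    randomForest,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
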