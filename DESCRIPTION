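Package: psnstack
Title: Patient-Similarity Networks, Centrality Feature Engineering and
    Stacked Ensemble Classification for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies records of a mixed-type clinical table by building,
    for every record, three weighted patient-similarity networks (over all
    training records, over positive-labelled records and over
    negative-labelled records), engineering seventeen node-centrality
    contrast features from the triple, and feeding them to a two-layer
    stacked ensemble whose members are chosen by validation accuracy and
    Q-statistic diversity and aggregated by validation-accuracy-weighted
    voting. Includes a synthetic-cohort generator emulating an intrauterine
    insemination registry, a preprocessing pipeline (missingness filtering,
    imputation, dummy coding, min-max scaling, correlation filtering,
    stratified folds, minority oversampling), leave-one-feature-out mean
    decrease in accuracy ranking, partial dependence, and the A-Test
    balanced K-fold structural-risk procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    stats,
    utils,
    e1071,
    rpart,
    ranger,
    xgboost,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
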