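Package: vitiphen
Title: Grapevine Phenology Staging from Satellite Time Series with
    Metaheuristic-Tuned Lightweight Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling grapevine phenological stages (budburst,
    flowering, veraison, harvest) from biweekly vegetation-index and rainfall
    time series. Includes a seeded synthetic site-season generator driven by
    growing-degree-day staging, quality control and gap-length-adaptive
    imputation of vegetation indices, pseudo-image construction for
    convolutional classification, a depthwise-separable convolutional network
    with dynamic class-weighted losses trained in pure R, a hybrid
    dream-optimizer / particle-swarm hyperparameter search, rule-based rain
    and pest risk alerting with event-matching validation, and an evaluation
    harness with grouped cross-validation, bootstrap intervals and
    permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
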