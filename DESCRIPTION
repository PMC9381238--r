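Package: cropgraph
Title: Graph-Based Suitability Evaluation for Crop Variety Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the suitability of crop varieties at
    multi-environment trial sites from phenotypic traits and growth-period
    climate summaries. Provides a calibrated synthetic trial-data generator
    (point-biserial feature-label correlations, site-clustered climate,
    injected outliers and missingness), outlier screening and scaling,
    Pearson feature screening, chord-distance k-nearest-neighbour graph
    construction, a from-scratch transductive graph convolutional classifier
    with label-budget training, a graph attention baseline, classical
    machine-learning baselines, five-metric repeated evaluation, and
    feature-ablation experiment harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    class,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
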