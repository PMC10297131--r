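Package: ckdfusion
Title: Graph-Tabular Fusion Deep Learning for Chronic Kidney Disease Prediction
Version: 0.1.0
Authors@R: person("CKD", "Fusion Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts chronic kidney disease (CKD) status from routine clinical
    features by fusing two learners: a graph convolutional network (GCN) run on
    a weighted k-nearest-neighbour patient-similarity graph, and a feed-forward
    network on the tabular feature matrix, combined by an averaging late-fusion
    head. Ships the full preprocessing chain used for the UCI CKD table
    (missing-value imputation, IQR winsorization, min-max normalization, and a
    from-scratch SMOTE oversampler), deterministic stratified splitting, seeded
    training with SGD or Adam and manual backpropagation, grid-search tuning,
    confusion-matrix metrics, a synthetic CKD-like data generator, and a
    config-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
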