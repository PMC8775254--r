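Package: cffemg
Title: Concatenate Feature Fusion Networks for Surface-EMG Gesture Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multichannel surface-electromyography (sEMG) hand-gesture
    recognition built around the concatenate feature fusion (CFF) strategy: a
    dimensionality-reduction block that applies a parameter-free max-pooling
    branch and a trainable 2-stride convolution branch in parallel and
    concatenates their channels, so both signal amplitude and temporal context
    survive the reduction. The package provides sliding-window segmentation and
    frame reshaping of labeled recordings, the analytic CFF primitives
    (featurewise max-pooling, feature-mixing strided convolution, receptive-field
    arithmetic, collision construction), trainable RCNN and CFF-RCNN classifiers
    with a self-contained gradient-checked network engine, classic time-domain
    EMG features (MAV, ZC, SSC, WL) with shallow PCA/LDA/KNN and dense-network
    baselines, a synthetic sEMG generator with order-confusable class pairs, and
    experiment utilities: stratified k-fold cross-validation, exact Wilcoxon
    signed-rank model comparison, and convergence-efficiency reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
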