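Package: histotile
Title: Tile-Based Whole-Slide Image Classification for NSCLC Subtyping
Version: 0.1.0
Authors@R: person("Histotile", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, fully testable re-implementation of a tile-based
    deep-learning pipeline that classifies non-small cell lung cancer slides
    into squamous versus non-squamous subtypes. Provides seeded synthetic
    virtual-biopsy slide generation, fixed 220-pixel tiling with white
    background removal, Reinhard colour normalization in l-alpha-beta space,
    slide-grouped data splitting, a small native convolutional network with
    weighted cross-entropy, confidence thresholding by grid search, spatial
    re-estimation of tile probabilities with a logistic-regression filter
    kernel, slide-level aggregation by majority vote or max pooling, virtual
    tissue-microarray gating from annotation centroids, and accuracy/ROC
    evaluation with heatmap rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
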