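Package: hypernet
Title: Hypernetwork Integration and Classification of Paired Multi-Omic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Integrated analysis of paired (crossover) multi-omic studies:
    per-layer normalization and per-subject paired differences, paired
    differential expression with false discovery rate control, hypernetwork
    integration of differentially expressed elements against all elements
    called present (thresholded-correlation incidence matrix, shared-edge
    adjacency M times t(M), chi-squared signal-window threshold selection,
    hierarchical central-cluster extraction, and a dissimilarity robustness
    filter), and downstream classification (PLS-DA separation,
    shadow-permutation feature selection, random forest out-of-bag AUC).
    Includes a synthetic-data generator for paired crossover multi-omic
    studies with planted condition effects and cross-layer latent factors,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    randomForest,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
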