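Package: sspca
Title: Semisupervised Principal Component Analysis for Single-Cell Cluster Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cluster-aware 2-D/3-D embedding of single-cell RNA-seq data by
    semisupervised principal component analysis (ssPCA). Given a cell-cell
    similarity (kernel) matrix and cluster labels, ssPCA finds an orthonormal
    projection maximizing a lambda-weighted combination of total variance and
    Hilbert-Schmidt Independence Criterion (HSIC) cluster dependence, solved in
    closed form by symmetric eigendecomposition. Includes kernel constructors
    (linear, polynomial, RBF with median-heuristic bandwidth), a branching-tree
    data simulator for evaluation, structure-preservation metrics (k-NN label
    agreement, centroid-distance rank correlation, silhouette), readers and
    writers for dense and MatrixMarket matrices, broom-style tidiers, and
    ggplot2 visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
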