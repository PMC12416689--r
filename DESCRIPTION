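Package: acgsfe
Title: Adaptive Cluster-Guided SFE Feature Selection for High-Dimensional
    Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid filter-wrapper feature selection for expression-like data
    with many more features than samples. Implements the adaptive
    cluster-guided SFE search: a single-agent wrapper with non-selection and
    selection operators, Ward hierarchical clustering of the feature
    correlation matrix with data-driven choice of the number of clusters
    (normalized Davies-Bouldin and Silhouette scores), and adaptive mutual
    information based intra-cluster regularization with a shrinking
    per-cluster feature cap. Includes stratified train/test and k-fold
    splitting, a 1-NN cross-validated fitness, a synthetic block-correlated
    data generator for end-to-end testing, and evaluation metrics (accuracy,
    F-measure, train-test RMSE, feature reduction rate, Jaccard stability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
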