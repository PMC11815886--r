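Package: pairclass
Title: Rank-Based Gene-Pair Features for Cross-Platform Cluster Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcriptomic cluster-label classifiers from within-sample
    gene-pair rank comparisons, which are invariant to any strictly increasing
    per-sample transform and therefore transfer between expression platforms
    (e.g., microarray and RNA-seq). Provides proportion-difference scoring and
    greedy correlation-capped selection of gene-pair features, per-cluster
    ensembles of binary gradient-boosted learners with a best-call
    meta-predictor, stratified cross-validation with in-fold feature selection,
    platform-transfer and round-trip label validation, cross-dataset feature
    aggregation by information gain, Kaplan-Meier/log-rank survival
    stratification of predicted clusters, and a single-cell dotplot-style check
    that localizes a pair's expression reversal to a cell type. Includes
    synthetic-cohort generators with planted gene-pair reversals, matched
    platform-distorted views, cluster-dependent survival, and zero-inflated
    single-cell counts for property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
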