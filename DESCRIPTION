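Package: strataminer
Title: Data-Driven Stratified Sampling Design from Multi-Indicator District Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs stratified survey samples by mining multi-indicator
    health data of geographic units (districts nested in provinces).
    Provides Hopkins-statistic clustering-tendency testing, Gaussian
    mixture model-based clustering with BIC model selection across six
    covariance parameterizations, complete-linkage hierarchical clustering
    with a majority-vote ensemble for choosing the number of clusters,
    internal (within-cluster sum of squares, silhouette, Dunn) and
    leave-one-column-out stability (APN, AD, ADM, FOM) validity indices,
    decision-tree extraction of human-readable cluster partitioning rules,
    province-to-cluster assignment with medoid-province selection, and a
    Monte-Carlo comparison of the sampling efficiency of cluster-stratified
    designs against simple random sampling. A synthetic-data generator with
    known latent cluster structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
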