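Package: habitraits
Title: Trait-Based Functional Analysis of Human Microbiome Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the functional composition of host-associated
    microbial communities from a curated trait database and relative-abundance
    profiles. Computes abundance-weighted community trait profiles, permutation
    tests for pairwise trait differences between body sites with cross-phylum
    replication, phylogenetically blocked cross-validation of random-forest
    models (Cohen's kappa, precision-recall AUC), sparse trait co-occurrence
    networks by graphical lasso with extended-BIC selection, signed spin-glass
    community detection, bipartite cluster-site association networks,
    phylogenetic logistic regression with parametric-bootstrap inference, and
    an entropy decomposition of community metabolic breadth. Includes a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    randomForest,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
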