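Package: spatialTME
Title: Multi-Scale Spatial Statistics for the Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("TME", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts non-spatial, local, radius-based and global spatial
    statistics from marked cell-coordinate point patterns produced by
    multiplex immunofluorescence phenotyping, standardizes the radius-based
    F, G, K and L functions against seeded Monte-Carlo complete-spatial-
    randomness nulls matched to each region's window and counts, assembles
    missing-aware patient-level feature matrices with filtering and median
    imputation, and runs downstream unsupervised (consensus non-negative
    matrix factorization with Brunet updates, hierarchical clustering) and
    supervised (random forest with out-of-bag AUC and joint permutation
    importance, Kaplan-Meier/log-rank survival) analyses. Includes marked
    point-process simulators (CSR, Thomas clusters, hard-core inhibition,
    cross-type attraction/repulsion) and a synthetic-cohort generator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
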