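Package: latentsig
Title: Sparse Multivariate Projection Methods for Multi-Omics Signature Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised multivariate projection methods for molecular
    signature discovery in omics data. Implements sparse partial least
    squares discriminant analysis (sPLS-DA) for a single data set,
    multi-block sPLS-DA for joint integration of several omics blocks
    measured on the same samples (N-integration), and multi-group sPLS-DA
    for integrating independent studies measuring the same predictors
    (P-integration), all instantiated from one generic alternating
    least-squares engine with soft-thresholding feature selection (keepX).
    Includes class prediction with maximum, centroid and Mahalanobis
    distances, majority and weighted voting across blocks, repeated
    stratified and leave-one-group-out cross-validation for tuning keepX
    and the number of components, performance and feature-stability
    assessment with one-vs-all ROC/AUC, NIPALS principal component
    analysis tolerant to missing values, numeric backends for the usual
    projection plots, seeded synthetic multi-omics generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    parallel
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC
Config/testthat/edition: 3
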