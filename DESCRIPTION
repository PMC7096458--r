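Package: semicam
Title: Semi-Supervised Deconvolution of Bulk Transcriptomes with Partial Marker Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage semi-supervised deconvolution of bulk gene expression
    data into cell-type-specific signatures and mixing proportions when marker
    genes are known for only a subset of the cell types. Stage one extends
    convex analysis of mixtures (CAM) with marker-anchored k-means clustering
    and an exhaustive simplex-vertex search to discover marker genes for every
    cell type; stage two estimates cell proportions by marker-constrained
    non-negative matrix factorization under a generalized Kullback-Leibler
    objective with sum-to-one proportions. Includes gene filtering, marker
    selection from pure-cell replicate profiles, a heteroscedastic mixture
    simulator, component matching, and accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
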