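Package: consenet
Title: Consensus Inference of Microbial Association Networks via Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sparse, reproducible microbial association networks from
    count abundance tables by combining several Gaussian graphical model
    estimators (graphical lasso, neighborhood selection, tree averaging) under
    a modified stability-selection scheme. Edge selection frequencies computed
    over resamples are harmonized across methods by network density under a
    mean-stability constraint and merged into a single consensus network via
    mean, 2-norm, inverse-variance weighted or vote-count summaries. Includes
    a Gaussian-copula simulator of zero-inflated overdispersed counts with a
    known conditional-dependence graph, and precision/recall evaluation
    utilities for benchmarking edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
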