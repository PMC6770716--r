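Package: pkboost
Title: Pathway-Based Kernel Boosting for Binary Phenotype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of genomic samples by boosting over
    pathway-restricted kernel base learners. At each iteration a second-order
    (Newton-style) approximation of the empirical log loss is minimized within
    every pathway's kernel function space under an L1 (LASSO) or L2 (ridge)
    penalty on the kernel combination coefficients; the best-fitting pathway's
    learner is added to the additive log-odds model after an exact line search.
    The Euclidean norms of each pathway's aggregated coefficients provide
    pathway importance weights. Includes GMT/TSV input handling, nested
    cross-validation for the stopping iteration, automatic penalty-parameter
    selection with a geometric grid, a simulation module for benchmarking, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
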