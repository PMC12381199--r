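Package: bayespgls
Title: Bayesian Phylogenetic Regression over Samples of Dated Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits lambda-scaled phylogenetic generalized least squares (PGLS)
    regressions by Markov chain Monte Carlo, repeats each model over a sample of
    dated phylogenies to propagate topological and dating uncertainty, and
    aggregates per-tree posterior summaries into cross-tree significance verdicts
    using the proportion-of-posterior-crossing-zero statistic. Includes a
    phylogenetic imputation procedure that predicts a held-out taxon's trait from
    the fitted regression and its position on the tree, a multi-tree outlier test
    built on the predictive tail mass, and a synthetic-data generator (Yule trees,
    jittered tree samples, correlated trait evolution under lambda-scaled Brownian
    motion) so the whole pipeline can be exercised and calibrated without access
    to restricted morphological data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
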