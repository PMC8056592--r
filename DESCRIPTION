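Package: longicluster
Title: Ensemble Integrative Clustering of Longitudinal Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats the time points of a longitudinal gene-expression study
    as the views of an integrative clustering problem. Fits a joint
    latent-variable (factor-analysis) model across time points by EM with
    optional soft-threshold shrinkage of the loadings, and builds an
    ensemble of such fits on small random gene subsets: weak learners are
    kept when their cluster labels agree with a binary response label above
    an accuracy cutoff, genes are scored by their summed absolute loadings
    over the kept learners, and subject-level class predictions are made by
    majority vote. Includes a supervised evaluation layer (time-averaged
    pseudo-gene covariates, leave-one-out support-vector-machine accuracy
    with per-fold ensemble retraining, a random-gene-set baseline), a
    LASSO-ensemble and single-fit comparator, group mean trajectory
    summaries with gap-closure ratios against a non-lesional reference, and
    a synthetic longitudinal data generator with planted informative genes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
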