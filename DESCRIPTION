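Package: drpaudit
Title: Composition Audits for Drug-Blind Cancer Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing how the composition of monotherapy
    pharmacogenomic training panels drives drug-blind generalization of
    drug response prediction (DRP) models. Implements permutation-null
    baselines (intradrug and intracell response shuffles, one-hot cell
    controls), cells-per-drug diversity capping, fixed-test and partially
    drug-blind composition sweeps, elastic-net meta-regression of model
    performance on training-set composition, relationship statistics on
    the resulting predictor-by-target coefficient matrix (one-to-one,
    many-to-one, class-to-class, self-best rate), and mechanism-isolated
    training comparisons. A two-arm multilayer perceptron DRP model and a
    mechanism-structured synthetic pharmacogenomic panel generator with
    known ground truth make every stage runnable end-to-end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    yaml,
    ggplot2,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
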