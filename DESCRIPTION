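Package: aievote
Title: Multi-Modal Ensemble Voting for AIE/ACQ Prediction from SMILES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a small organic molecule is
    aggregation-induced-emission (AIE) active or shows
    aggregation-caused quenching (ACQ), from its SMILES string alone.
    Implements four hashed 2048-bit topological fingerprints (Morgan
    circular, linear-path, atom-pair, topological torsion), a
    108-dimensional 1D/2D quantitative descriptor block, PCA-based
    multi-modal feature fusion with z-score standardisation, five
    tuned classifier families (logistic regression, k-nearest
    neighbours, gradient boosting, random forest, multilayer
    perceptron) with nested cross-validation, and a hard-label
    majority-voting ensemble over all (classifier, feature mode)
    combinations. Includes a synthetic SMILES generator with a
    planted rotor-based structure-to-label rule for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    class,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
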