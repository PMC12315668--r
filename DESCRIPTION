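Package: clpnet
Title: Cross-Lagged Panel Networks via Regularized Node-Wise Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates three-wave at-risk adolescent cohorts with known sparse
    cross-lagged dynamics, high-risk oversampling, informative attrition and
    task-level measurement realism; applies the preprocessing rules used for
    CBCL/ABCL symptom scales and executive-function tasks (outlier removal,
    orientation inversion, working-memory aggregation, instrument
    harmonization); estimates cross-lagged panel networks wave-pair by
    wave-pair with node-wise LASSO regressions (from-scratch coordinate
    descent, 10-fold cross-validated penalty, predictor-only covariates);
    quantifies edge accuracy by nonparametric bootstrap; and classifies
    executive-function/psychopathology links as risk factors, consequences, or
    both. Includes parameter-recovery experiments against generator truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
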