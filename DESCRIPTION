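Package: lagnet
Title: Gene Regulatory Network Inference with the Time-Lagged Ordered Lasso
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from time-course
    expression data by fitting per-gene lagged linear models with an l1
    penalty and a monotone non-increasing constraint on coefficient
    magnitudes across lags, so that the influence of a predictor decays
    with temporal distance. Provides de novo inference, a semi-supervised
    variant that embeds a prior network through separate penalties for
    prior edges and non-edges, pairwise Granger-causality and Lasso-Granger
    baselines, a repressilator oscillator and sparse vector-autoregression
    simulators for validation, and merged-lambda ROC/AUC evaluation of
    regularization-path edge rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
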