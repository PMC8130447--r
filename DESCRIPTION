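Package: effectscore
Title: Deterministic Effect Scores for Interpreting Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-agnostic interpretation of binary-outcome clinical risk
    models through deterministic effect scores: per-patient logit differences
    between a model's prediction at the observed feature value and at a chosen
    reference value (for example, a comorbidity absent, or age 40), averaged
    within distinct observed values and aggregated into a per-feature score
    that supports ranking of categorical risk factors and LOWESS-smoothed
    effect profiles of continuous ones. Includes a synthetic electronic health
    record cohort simulator with correlated binary comorbidities and known
    generative coefficients, a bootstrap/split/cross-validated model-fitting
    pipeline over a zoo of logistic regression, random forest, gradient
    boosting and neural network models, and baseline explainers (permutation
    importance and exact enumeration Shapley values in logit space) for
    comparison under correlated predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
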