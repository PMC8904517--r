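Package: slhte
Title: Super Learner Transfer and Responder Subgroup Analysis for Paired
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heterogeneous treatment effects across two randomized
    trials that share a covariate schema. An ensemble outcome model (Super
    Learner: cross-validated base learners stacked by non-negative least
    squares) is trained on the treated arm of a source trial to predict
    clinically significant HbA1c improvement, transferred to a target trial
    to score each patient's responder probability, and probability cut-offs
    are swept to form nested subgroups in which the covariate-adjusted
    treatment effect is estimated. Includes a synthetic twin-trial generator
    calibrated to published marginal summaries, chained-equations imputation
    with random-forest draws for target-trial covariates, and tidy
    reporting and plotting of the cut-off sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
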