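Package: strokeITE
Title: Causal Effect and Individualized Treatment Effect Estimation for
    Stroke Prevention Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating average and individualized causal effects
    of stroke risk factors and antiplatelet treatment from observational
    cohort data.  Provides a structural-causal-model cohort simulator with
    exact per-patient ground truth, backdoor adjustment-set identification
    on a clinical causal diagram, propensity-score estimators
    (stratification, inverse probability weighting, doubly robust
    augmented IPW), cross-fitted double machine learning in linear and
    gradient-boosted variants, natural direct/indirect effect mediation via
    the mediational g-formula, a three-headed neural potential-outcome
    network (Dragonnet) with targeted regularization, and nested weighted
    split-conformal quantile regression for per-patient treatment-effect
    intervals with finite-sample coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    glmnet,
    xgboost,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
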