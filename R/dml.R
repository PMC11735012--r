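# Double machine learning for the average treatment effect.
#
# K-fold cross-fitting with the interactive (AIPW-type) Neyman-orthogonal
# score for a binary treatment: nuisances are fitted on K-1 folds and the
# score evaluated on the held-out fold, so every observation is scored
# exactly once by models that never saw it.  The ATE solves the averaged
# score; the standard error comes from the empirical influence function.
# Fold assignment is repeated over a few seeds and the median estimate
# reported, which stabilizes the (small) partition randomness.

#' Configure a DML run
#'
#' @param n_folds number of cross-fitting folds (>= 2; default 5).
#' @param variant \code{"linear"} (L1-penalized logistic outcome models,
#'   logistic-regression propensity) or \code{"nonlinear"}
#'   (gradient-boosted trees for both).
#' @param seed base seed; repetition r uses \code{seed + r - 1}.
#' @param n_rep number of fold-assignment repetitions whose median is
#'   reported (default 3).
#' @param xgb_params list of gradient-boosting settings for the nonlinear
#'   variant: \code{max_depth}, \code{nrounds}, \code{eta}.
#' @param outcome_learner,propensity_learner optional custom nuisance
#'   fitters, each a \code{function(x_train, y_train, x_test)} returning
#'   predicted means/probabilities for \code{x_test}; overrides the
#'   variant's default learners.
#' @return an object of class \code{dml_config}.
#' @export
dml_config <- function(n_folds = 5L, variant = c("linear", "nonlinear"),
                       seed = 1L, n_rep = 3L,
                       xgb_params = list(max_depth = 3L, nrounds = 200L,
                                         eta = 0.1),
                       outcome_learner = NULL, propensity_learner = NULL) {
  variant <- match.arg(variant)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  structure(list(n_folds = as.integer(n_folds), variant = variant,
                 seed = as.integer(seed), n_rep = as.integer(n_rep),
                 xgb_params = xgb_params,
                 outcome_learner = outcome_learner,
                 propensity_learner = propensity_learner),
            class = "dml_config")
}

xgb_learner <- function(params, objective) {
  function(x_train, y_train, x_test) {
    booster <- xgboost::xgb.train(
      params = list(objective = objective, max_depth = params$max_depth,
                    eta = params$eta, nthread = 1L),
      data = xgboost::xgb.DMatrix(x_train, label = y_train),
      nrounds = params$nrounds, verbose = 0L)
    as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(x_test)))
  }
}

lasso_learner <- function(family) {
  function(x_train, y_train, x_test) {
    if (length(unique(y_train)) == 1L)
      return(rep(y_train[1L], nrow(x_test)))
    if (nrow(x_train) < 50L || ncol(x_train) < 2L) {
      df <- data.frame(y = y_train, x_train)
      fit <- stats::glm(y ~ ., data = df,
                        family = if (family == "binomial")
                          stats::binomial() else stats::gaussian())
      return(as.numeric(stats::predict(fit, data.frame(x_test),
                                       type = "response")))
    }
    fit <- glmnet::cv.glmnet(x_train, y_train, family = family, nfolds = 5L)
    as.numeric(stats::predict(fit, newx = x_test, s = "lambda.min",
                              type = "response"))
  }
}

logit_learner <- function() {
  function(x_train, y_train, x_test) {
    df <- data.frame(y = y_train, x_train)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    as.numeric(stats::predict(fit, data.frame(x_test), type = "response"))
  }
}

dml_learners <- function(config, outcome_binary) {
  out <- config$outcome_learner
  prop <- config$propensity_learner
  if (is.null(out))
    out <- if (config$variant == "nonlinear")
      xgb_learner(config$xgb_params,
                  if (outcome_binary) "binary:logistic" else "reg:squarederror")
    else lasso_learner(if (outcome_binary) "binomial" else "gaussian")
  if (is.null(prop))
    prop <- if (config$variant == "nonlinear")
      xgb_learner(config$xgb_params, "binary:logistic")
    else logit_learner()
  list(outcome = out, propensity = prop)
}

dml_folds <- function(a, k, seed) {
  for (attempt in 0:1) {
    folds <- with_seed(seed + 1000L * attempt,
                       sample(rep_len(seq_len(k), length(a))))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(a[folds == f])) == 2L, logical(1)))
    if (ok) return(folds)
  }
  stop("a cross-fitting fold lacks one exposure arm even after refolding")
}

#' Cross-fitted double machine learning ATE
#'
#' Estimates the average treatment effect with the interactive orthogonal
#' score \eqn{\psi_i = m_1(X_i) - m_0(X_i) + A_i (Y_i - m_1(X_i))/e(X_i) -
#' (1-A_i)(Y_i - m_0(X_i))/(1-e(X_i))}, all nuisances cross-fitted.
#' Supplying \code{m1}, \code{m0} and \code{e} bypasses cross-fitting and
#' evaluates the score at those nuisances (the oracle/plug-in reduction).
#'
#' @inheritParams sps_ate
#' @param config a \code{\link{dml_config}}.
#' @param m1,m0,e optional fixed nuisance vectors (oracle mode).
#' @return an \code{\link{effect_estimate}} (risk difference); the point is
#'   the median over \code{config$n_rep} fold-assignment repetitions, the
#'   standard error the median influence-function SE, and
#'   \code{details$reps} holds the per-repetition estimates.
#' @export
dml_ate <- function(cohort, exposure, adjustment, outcome = "y",
                    config = dml_config(), m1 = NULL, m0 = NULL, e = NULL) {
  stopifnot(inherits(config, "dml_config"))
  a <- cohort[[exposure]]; y <- cohort[[outcome]]
  check_binary(a, "exposure")
  n <- length(a)
  if (!is.null(m1) && !is.null(m0) && !is.null(e)) {
    psi <- m1 - m0 + a * (y - m1) / e - (1 - a) * (y - m0) / (1 - e)
    return(effect_estimate(paste0("dml-", config$variant), exposure,
                           mean(psi), stats::sd(psi) / sqrt(n)))
  }
  if (length(adjustment) == 0L) stop("adjustment set must be nonempty")
  x <- as.matrix(cohort[, adjustment, drop = FALSE])
  outcome_binary <- all(y %in% c(0, 1))
  learners <- dml_learners(config, outcome_binary)
  one_rep <- function(rep_seed) {
    folds <- dml_folds(a, config$n_folds, rep_seed)
    m1_hat <- m0_hat <- e_hat <- numeric(n)
    for (f in seq_len(config$n_folds)) {
      te <- folds == f; tr <- !te
      m1_hat[te] <- learners$outcome(x[tr & a == 1, , drop = FALSE],
                                     y[tr & a == 1], x[te, , drop = FALSE])
      m0_hat[te] <- learners$outcome(x[tr & a == 0, , drop = FALSE],
                                     y[tr & a == 0], x[te, , drop = FALSE])
      e_hat[te] <- learners$propensity(x[tr, , drop = FALSE], a[tr],
                                       x[te, , drop = FALSE])
    }
    e_hat <- pmin(pmax(e_hat, 0.01), 0.99)
    psi <- m1_hat - m0_hat + a * (y - m1_hat) / e_hat -
      (1 - a) * (y - m0_hat) / (1 - e_hat)
    c(ate = mean(psi), se = stats::sd(psi) / sqrt(n))
  }
  reps <- vapply(seq_len(config$n_rep),
                 function(r) one_rep(config$seed + r - 1L), numeric(2))
  effect_estimate(paste0("dml-", config$variant), exposure,
                  stats::median(reps["ate", ]),
                  stats::median(reps["se", ]),
                  details = list(reps = reps["ate", ],
                                 n_folds = config$n_folds))
}
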