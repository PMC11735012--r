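# Propensity-score-based average treatment effect estimators.
#
# All estimators consume a cohort data frame with binary exposure and
# outcome columns, estimate effects on the risk-difference scale (except
# the odds-ratio baseline), and report an influence-function or
# stratification-based standard error; percentile-bootstrap confidence
# intervals are available on request.

#' Construct an effect estimate
#'
#' Container for a single estimator result.
#'
#' @param estimator estimator name.
#' @param exposure exposure node.
#' @param point point estimate.
#' @param se analytic standard error (may be \code{NA}).
#' @param ci_low,ci_high 95\% interval bounds (may be \code{NA}).
#' @param scale one of \code{"risk-difference"}, \code{"risk-ratio"},
#'   \code{"odds-ratio"}.
#' @param details optional list of estimator-specific extras.
#' @return an object of class \code{effect_estimate}.
#' @export
effect_estimate <- function(estimator, exposure, point, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            scale = "risk-difference", details = list()) {
  stopifnot(is.finite(point))
  structure(list(estimator = estimator, exposure = exposure,
                 point = point, se = se, ci_low = ci_low, ci_high = ci_high,
                 scale = scale, details = details),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  ci <- if (is.finite(x$ci_low))
    sprintf(" (95%% CI %.4g to %.4g)", x$ci_low, x$ci_high) else ""
  cat(sprintf("%s [%s] %s: %.4g%s\n", x$estimator, x$exposure, x$scale,
              x$point, ci))
  invisible(x)
}

#' @export
coef.effect_estimate <- function(object, ...) {
  stats::setNames(object$point, object$exposure)
}

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) stop(what, " must be coded 0/1")
  if (length(unique(x)) < 2L) stop(what, " is constant; no contrast exists")
  invisible(TRUE)
}

#' Fit a propensity-score model
#'
#' Logistic regression of the exposure on the adjustment covariates, with
#' fitted probabilities clipped away from 0 and 1 to tame inverse-weight
#' variance.
#'
#' @param cohort cohort data frame.
#' @param exposure name of the binary exposure column.
#' @param adjustment character vector of covariate columns.
#' @param clip two-element clipping bounds (default \code{c(0.01, 0.99)}).
#' @return an object of class \code{propensity_scores}: list with \code{e}
#'   (clipped scores), \code{fit} (the glm) and \code{model_description}.
#' @export
fit_propensity <- function(cohort, exposure, adjustment,
                           clip = c(0.01, 0.99)) {
  stopifnot(all(adjustment %in% names(cohort)), exposure %in% names(cohort))
  check_binary(cohort[[exposure]], paste0("exposure '", exposure, "'"))
  if (length(adjustment) == 0L) {
    e <- rep(mean(cohort[[exposure]]), nrow(cohort))
    desc <- "marginal exposure rate (empty adjustment set)"
    fit <- NULL
  } else {
    f <- stats::reformulate(adjustment, response = exposure)
    fit <- stats::glm(f, data = cohort, family = stats::binomial())
    e <- stats::fitted(fit)
    desc <- paste("logistic regression on",
                  paste(adjustment, collapse = ", "))
  }
  structure(list(e = pmin(pmax(e, clip[1L]), clip[2L]),
                 fit = fit, model_description = desc, clip = clip),
            class = "propensity_scores")
}

#' @export
print.propensity_scores <- function(x, ...) {
  cat("propensity_scores:", x$model_description, "\n")
  print(summary(x$e))
  invisible(x)
}

# recursive bisection of the propensity axis; a split is accepted only when
# both children keep >= min_per_arm patients in each exposure arm
sps_strata <- function(e, a, min_per_arm = 10L) {
  stratum <- integer(length(e))
  nxt <- 1L
  ok <- function(idx) sum(a[idx] == 1) >= min_per_arm &&
    sum(a[idx] == 0) >= min_per_arm
  recurse <- function(idx, lo, hi) {
    mid <- (lo + hi) / 2
    left <- idx[e[idx] <= mid]
    right <- idx[e[idx] > mid]
    if (hi - lo > 1e-6 && ok(left) && ok(right)) {
      recurse(left, lo, mid)
      recurse(right, mid, hi)
    } else {
      stratum[idx] <<- nxt
      nxt <<- nxt + 1L
    }
  }
  recurse(seq_along(e), 0, 1)
  stratum
}

#' Stratified propensity-score ATE
#'
#' Bins patients on the estimated propensity score by recursive bisection of
#' the unit interval; a bisection is accepted only while every resulting
#' stratum keeps at least \code{min_per_arm} exposed and unexposed patients,
#' so the number of strata adapts to the data.  The ATE is the
#' stratum-size-weighted mean of within-stratum outcome differences.
#'
#' @inheritParams fit_propensity
#' @param outcome name of the binary outcome column.
#' @param min_per_arm per-stratum floor for each arm (default 10).
#' @param propensity optional \code{propensity_scores} object to reuse.
#' @param ci if \code{TRUE}, adds a percentile-bootstrap 95\% interval.
#' @param B,seed bootstrap replicates and seed.
#' @return an \code{\link{effect_estimate}} (risk difference).
#' @export
sps_ate <- function(cohort, exposure, adjustment, outcome = "y",
                    min_per_arm = 10L, propensity = NULL,
                    ci = FALSE, B = 500L, seed = 1L) {
  point_fn <- function(data) {
    ps <- if (is.null(propensity) || !identical(data, cohort))
      fit_propensity(data, exposure, adjustment) else propensity
    a <- data[[exposure]]; y <- data[[outcome]]
    s <- sps_strata(ps$e, a, min_per_arm)
    tab <- split(seq_along(s), s)
    est <- 0; varsum <- 0; n <- length(a)
    for (idx in tab) {
      n1 <- sum(a[idx] == 1); n0 <- sum(a[idx] == 0)
      if (n1 == 0L || n0 == 0L)
        stop("stratum without both exposure arms: positivity failure")
      w <- length(idx) / n
      d <- mean(y[idx][a[idx] == 1]) - mean(y[idx][a[idx] == 0])
      est <- est + w * d
      v1 <- stats::var(y[idx][a[idx] == 1]); if (is.na(v1)) v1 <- 0
      v0 <- stats::var(y[idx][a[idx] == 0]); if (is.na(v0)) v0 <- 0
      varsum <- varsum + w^2 * (v1 / n1 + v0 / n0)
    }
    c(point = est, se = sqrt(varsum))
  }
  res <- point_fn(cohort)
  out <- effect_estimate("sps", exposure, res[["point"]], res[["se"]])
  if (ci) {
    b <- bootstrap_ci(function(d) point_fn(d)[["point"]], cohort,
                      B = B, seed = seed)
    out$ci_low <- b[["ci_low"]]; out$ci_high <- b[["ci_high"]]
  }
  out
}

#' Inverse-probability-weighted ATE
#'
#' Horvitz-Thompson estimator
#' \code{mean(A*Y/e) - mean((1-A)*Y/(1-e))}; with \code{stabilized = TRUE}
#' the Hajek (normalized-weight) variant is used instead.  A warning is
#' raised when the largest weight exceeds n/10.
#'
#' @inheritParams sps_ate
#' @param stabilized use normalized (Hajek) weights.
#' @return an \code{\link{effect_estimate}} (risk difference) with an
#'   influence-function standard error.
#' @export
ipw_ate <- function(cohort, exposure, adjustment, outcome = "y",
                    stabilized = FALSE, propensity = NULL,
                    ci = FALSE, B = 500L, seed = 1L) {
  point_fn <- function(data, warn = FALSE) {
    ps <- if (is.null(propensity) || !identical(data, cohort))
      fit_propensity(data, exposure, adjustment) else propensity
    a <- data[[exposure]]; y <- data[[outcome]]; e <- ps$e
    w <- a / e + (1 - a) / (1 - e)
    if (warn && max(w) > length(a) / 10)
      warning("extreme inverse-propensity weight (max ",
              signif(max(w), 3), ")")
    if (stabilized) {
      est <- sum(a * y / e) / sum(a / e) -
        sum((1 - a) * y / (1 - e)) / sum((1 - a) / (1 - e))
      inf <- a * (y - sum(a * y / e) / sum(a / e)) / e -
        (1 - a) * (y - sum((1 - a) * y / (1 - e)) / sum((1 - a) / (1 - e))) / (1 - e)
    } else {
      contrib <- a * y / e - (1 - a) * y / (1 - e)
      est <- mean(contrib)
      inf <- contrib - est
    }
    c(point = est, se = stats::sd(inf) / sqrt(length(a)))
  }
  res <- point_fn(cohort, warn = TRUE)
  out <- effect_estimate(if (stabilized) "ipw-stabilized" else "ipw",
                         exposure, res[["point"]], res[["se"]])
  if (ci) {
    b <- bootstrap_ci(function(d) point_fn(d)[["point"]], cohort,
                      B = B, seed = seed)
    out$ci_low <- b[["ci_low"]]; out$ci_high <- b[["ci_high"]]
  }
  out
}

# arm-specific outcome-regression fit: L1-penalized logistic regression
# (lambda by 5-fold CV) when the arm is large enough, plain logistic
# regression otherwise; returns predictions for all rows of `data`
fit_outcome_arm <- function(data, arm_rows, adjustment, outcome) {
  y <- data[[outcome]][arm_rows]
  if (length(adjustment) == 0L || length(unique(y)) == 1L)
    return(rep(mean(y), nrow(data)))
  fam <- if (all(data[[outcome]] %in% c(0, 1))) "binomial" else "gaussian"
  x <- as.matrix(data[, adjustment, drop = FALSE])
  if (length(arm_rows) >= 50L && ncol(x) >= 2L) {
    fit <- glmnet::cv.glmnet(x[arm_rows, , drop = FALSE], y,
                             family = fam, nfolds = 5L)
    as.numeric(stats::predict(fit, newx = x, s = "lambda.min",
                              type = "response"))
  } else {
    f <- stats::reformulate(adjustment, response = outcome)
    fit <- stats::glm(f, data = data[arm_rows, , drop = FALSE],
                      family = if (fam == "binomial") stats::binomial()
                      else stats::gaussian())
    as.numeric(stats::predict(fit, newdata = data, type = "response"))
  }
}

#' Doubly robust (augmented IPW) ATE
#'
#' Combines arm-specific outcome regressions (L1-penalized logistic
#' regression) with an inverse-propensity correction:
#' \deqn{mean[ m1(X) - m0(X) + A(Y - m1(X))/e - (1-A)(Y - m0(X))/(1-e) ].}
#' Consistent when either the outcome models or the propensity model is
#' correctly specified.  Either nuisance can be supplied directly (for
#' oracle plug-ins or deliberate misspecification studies) via \code{m1},
#' \code{m0}, \code{e}.
#'
#' @inheritParams sps_ate
#' @param m1,m0 optional per-patient outcome-model predictions under
#'   exposure and control.
#' @param e optional per-patient propensity scores.
#' @return an \code{\link{effect_estimate}} (risk difference) with the
#'   influence-function standard error.
#' @export
dre_ate <- function(cohort, exposure, adjustment, outcome = "y",
                    m1 = NULL, m0 = NULL, e = NULL,
                    ci = FALSE, B = 500L, seed = 1L) {
  fixed_m1 <- m1; fixed_m0 <- m0; fixed_e <- e
  point_fn <- function(data) {
    a <- data[[exposure]]; y <- data[[outcome]]
    e_ <- if (is.null(fixed_e))
      fit_propensity(data, exposure, adjustment)$e else fixed_e
    m1_ <- if (is.null(fixed_m1))
      fit_outcome_arm(data, which(a == 1), adjustment, outcome) else fixed_m1
    m0_ <- if (is.null(fixed_m0))
      fit_outcome_arm(data, which(a == 0), adjustment, outcome) else fixed_m0
    psi <- m1_ - m0_ + a * (y - m1_) / e_ - (1 - a) * (y - m0_) / (1 - e_)
    c(point = mean(psi), se = stats::sd(psi) / sqrt(length(psi)))
  }
  res <- point_fn(cohort)
  out <- effect_estimate("dre", exposure, res[["point"]], res[["se"]])
  if (ci) {
    b <- bootstrap_ci(function(d) point_fn(d)[["point"]], cohort,
                      B = B, seed = seed)
    out$ci_low <- b[["ci_low"]]; out$ci_high <- b[["ci_high"]]
  }
  out
}

#' Adjusted odds ratio from multivariable logistic regression
#'
#' The conventional epidemiological baseline: the exposure odds ratio from
#' \code{glm(outcome ~ exposure + adjustment, binomial)} with a Wald 95\%
#' interval.
#'
#' @inheritParams sps_ate
#' @return an \code{\link{effect_estimate}} on the odds-ratio scale.
#' @export
logistic_or_baseline <- function(cohort, exposure, adjustment,
                                 outcome = "y") {
  f <- stats::reformulate(c(exposure, adjustment), response = outcome)
  fit <- stats::glm(f, data = cohort, family = stats::binomial())
  beta <- stats::coef(fit)[[exposure]]
  se <- sqrt(stats::vcov(fit)[exposure, exposure])
  effect_estimate("logistic-or", exposure, exp(beta), se = exp(beta) * se,
                  ci_low = exp(beta - 1.96 * se),
                  ci_high = exp(beta + 1.96 * se),
                  scale = "odds-ratio",
                  details = list(log_or = beta, se_log = se))
}

#' Unadjusted difference in outcome means
#'
#' The naive exposed-minus-unexposed contrast, reported for comparison with
#' the confounding-adjusted estimators.
#'
#' @inheritParams sps_ate
#' @return an \code{\link{effect_estimate}} (risk difference).
#' @export
naive_difference <- function(cohort, exposure, outcome = "y") {
  a <- cohort[[exposure]]; y <- cohort[[outcome]]
  check_binary(a, "exposure")
  d <- mean(y[a == 1]) - mean(y[a == 0])
  se <- sqrt(stats::var(y[a == 1]) / sum(a == 1) +
               stats::var(y[a == 0]) / sum(a == 0))
  effect_estimate("naive", exposure, d, se)
}

#' Percentile-bootstrap confidence interval
#'
#' Nonparametric bootstrap over patients: \code{B} resamples with
#' replacement, the estimator re-run on each, and the percentile interval of
#' the resampled points returned.  Seeded and reproducible.  Errors if more
#' than 5\% of resamples fail.
#'
#' @param estimator a function taking a cohort data frame and returning a
#'   numeric scalar.
#' @param cohort cohort data frame.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return named numeric vector with \code{ci_low}, \code{ci_high}.
#' @export
bootstrap_ci <- function(estimator, cohort, B = 500L, seed = 1L,
                         level = 0.95) {
  if (B < 100L) stop("B must be at least 100")
  with_seed(seed, {
    n <- nrow(cohort)
    pts <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(estimator(cohort[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
    fail <- mean(is.na(pts))
    if (fail > 0.05)
      stop("estimator failed in ", round(100 * fail), "% of resamples")
    q <- stats::quantile(pts, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE, names = FALSE)
    c(ci_low = q[1L], ci_high = q[2L])
  })
}
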