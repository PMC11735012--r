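# Nested weighted split-conformal quantile regression for individual
# treatment-effect intervals.
#
# Stage 1 builds counterfactual outcome intervals with weighted
# split-conformal quantile regression: per-arm quantile regressors (pinball
# loss, gradient-boosted trees) are fitted on one part of the training
# split, conformity scores are calibrated on the other part with
# likelihood-ratio weights 1/e(x) (arm 1) or 1/(1-e(x)) (arm 0) that
# correct the covariate shift between the observed arm and the whole
# cohort.  Each patient's counterfactual interval is combined with their
# observed factual outcome into bounds on the individual treatment effect.
# Stage 2 (the nested step) regresses those bounds on the covariates and
# conformalizes the bound regressors on the held-out evaluation split, so
# the final intervals are defined for every covariate profile and retain a
# finite-sample marginal guarantee.  The total miscoverage budget alpha is
# split evenly between the two stages.

#' Configure the conformal ITE procedure
#'
#' @param alpha total miscoverage level (default 0.05 for 95\% intervals),
#'   split evenly between the counterfactual stage and the nested stage.
#' @param split_fraction fraction of the cohort in the training split
#'   (default 0.5: even train/evaluation split).
#' @param weight_mode \code{"inverse-propensity"} (default) weights
#'   calibration scores by the likelihood ratio between target and
#'   observed-arm covariate distributions; \code{"uniform"} reduces to
#'   standard split-CQR.
#' @param outcome outcome column the quantile regressors model: the binary
#'   stroke indicator \code{"y"} (coarse step-function quantiles) or the
#'   continuous latent risk \code{"y_latent"}.
#' @param quantile_learner gradient-boosting settings for the pinball-loss
#'   quantile regressors (\code{nrounds}, \code{max_depth}, \code{eta},
#'   \code{min_child_weight}).  The defaults use a larger step size and
#'   more rounds than a squared-error fit would need: the gradient of the
#'   pinball loss at extreme quantiles is tiny on one side, so a timid
#'   learner never reaches the conditional tail.
#' @param bound_learner settings for the squared-error bound regressors of
#'   the nested stage.
#' @param clip propensity clipping bounds for the conformal weights.
#' @param seed seed for all splits.
#' @return an object of class \code{conformal_config}.
#' @export
conformal_config <- function(alpha = 0.05, split_fraction = 0.5,
                             weight_mode = c("inverse-propensity", "uniform"),
                             outcome = "y",
                             quantile_learner = list(nrounds = 300L,
                                                     max_depth = 3L,
                                                     eta = 0.3,
                                                     min_child_weight = 20),
                             bound_learner = list(nrounds = 150L,
                                                  max_depth = 3L, eta = 0.1),
                             clip = c(0.01, 0.99), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, split_fraction > 0, split_fraction < 1)
  structure(list(alpha = alpha, split_fraction = split_fraction,
                 weight_mode = match.arg(weight_mode), outcome = outcome,
                 quantile_learner = quantile_learner,
                 bound_learner = bound_learner, clip = clip,
                 seed = as.integer(seed)),
            class = "conformal_config")
}

xgb_quantile_fit <- function(x, y, q, learner) {
  xgboost::xgb.train(
    params = list(objective = "reg:quantileerror", quantile_alpha = q,
                  max_depth = learner$max_depth, eta = learner$eta,
                  min_child_weight = learner$min_child_weight %||% 1,
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = learner$nrounds, verbose = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit per-arm conditional quantile bounds
#'
#' Gradient-boosted pinball-loss regressors of the outcome on the
#' covariates, within one treatment arm, at quantile levels
#' \code{alpha/2} and \code{1 - alpha/2}.  On binary outcomes the fitted
#' quantile surfaces are step functions of the predicted risk.
#'
#' @param cohort_train training rows.
#' @param arm 0 or 1: the treatment arm to model.
#' @param config a \code{\link{conformal_config}}.
#' @param covariates covariate columns; defaults to everything except the
#'   treatment and outcome columns.
#' @param exposure treatment column name.
#' @param alpha miscoverage level for this pair of quantiles (defaults to
#'   \code{config$alpha}).
#' @return an object of class \code{quantile_bounds} with boosters
#'   \code{lo}, \code{hi} and the covariate schema.
#' @export
fit_quantile_bounds <- function(cohort_train, arm, config,
                                covariates = NULL, exposure = "t",
                                alpha = config$alpha) {
  if (is.null(covariates))
    covariates <- setdiff(names(cohort_train),
                          c(exposure, "y", "y_latent"))
  rows <- cohort_train[[exposure]] == arm
  if (!any(rows)) stop("arm ", arm, " absent from the training split")
  x <- as.matrix(cohort_train[rows, covariates, drop = FALSE])
  y <- cohort_train[[config$outcome]][rows]
  structure(list(
    lo = xgb_quantile_fit(x, y, alpha / 2, config$quantile_learner),
    hi = xgb_quantile_fit(x, y, 1 - alpha / 2, config$quantile_learner),
    covariates = covariates, arm = arm, alpha = alpha),
    class = "quantile_bounds")
}

#' @rdname fit_quantile_bounds
#' @param models a fitted \code{quantile_bounds} object.
#' @param newdata data frame of rows to predict.
#' @return \code{predict_quantile_bounds}: data frame with columns
#'   \code{lo}, \code{hi} (\code{lo <= hi} enforced).
#' @export
predict_quantile_bounds <- function(models, newdata) {
  x <- as.matrix(newdata[, models$covariates, drop = FALSE])
  lo <- as.numeric(stats::predict(models$lo, xgboost::xgb.DMatrix(x)))
  hi <- as.numeric(stats::predict(models$hi, xgboost::xgb.DMatrix(x)))
  data.frame(lo = pmin(lo, hi), hi = pmax(lo, hi))
}

# smallest calibration score whose cumulative normalized weight reaches
# `level`, per test point (weight w0 on a point mass at +Inf); when the
# finite scores cannot carry the required mass the largest score is
# returned as a finite cap (documented approximation to the infinite
# interval)
weighted_score_quantile <- function(scores, weights, w0, level) {
  o <- order(scores)
  s <- scores[o]
  csw <- cumsum(weights[o])
  total <- csw[length(csw)]
  thr <- level * (total + w0)
  vapply(thr, function(th) {
    k <- which(csw >= th - 1e-12)[1L]
    if (is.na(k)) s[length(s)] else s[k]
  }, numeric(1))
}

#' Weighted conformal counterfactual intervals
#'
#' Given per-arm quantile models, computes conformity scores
#' \code{max(lo(x) - y, y - hi(x))} on calibration rows of the target arm
#' and, for each new patient, the weighted (1 - alpha) score quantile with
#' likelihood-ratio weights proportional to \code{1/e(x)} (arm 1) or
#' \code{1/(1 - e(x))} (arm 0), normalized per test point with the usual
#' point mass at infinity.  The returned interval for the counterfactual
#' outcome under \code{models$arm} is \code{[lo(x) - eta(x), hi(x) +
#' eta(x)]}.
#'
#' @param models a \code{quantile_bounds} fit for the target arm.
#' @param cohort_calib calibration rows (disjoint from the rows the models
#'   were fitted on).
#' @param newdata rows to produce intervals for.
#' @param config a \code{\link{conformal_config}}.
#' @param e_calib,e_new propensity scores P(T=1|X) for the calibration and
#'   new rows (ignored under uniform weights).
#' @param exposure treatment column name.
#' @param alpha miscoverage level (defaults to \code{models$alpha}).
#' @return data frame with columns \code{lo}, \code{hi}, \code{eta}.
#' @export
weighted_conformal_counterfactual <- function(models, cohort_calib, newdata,
                                              config, e_calib = NULL,
                                              e_new = NULL, exposure = "t",
                                              alpha = models$alpha) {
  arm <- models$arm
  rows <- which(cohort_calib[[exposure]] == arm)
  if (length(rows) < 25L)
    stop("fewer than 25 calibration points in arm ", arm)
  qc <- predict_quantile_bounds(models, cohort_calib[rows, , drop = FALSE])
  ycal <- cohort_calib[[config$outcome]][rows]
  scores <- pmax(qc$lo - ycal, ycal - qc$hi)
  if (config$weight_mode == "uniform") {
    w <- rep(1, length(rows))
    w0 <- rep(1, nrow(newdata))
  } else {
    if (is.null(e_calib) || is.null(e_new))
      stop("inverse-propensity weights require e_calib and e_new")
    ec <- pmin(pmax(e_calib[rows], config$clip[1L]), config$clip[2L])
    en <- pmin(pmax(e_new, config$clip[1L]), config$clip[2L])
    w <- if (arm == 1L) 1 / ec else 1 / (1 - ec)
    w0 <- if (arm == 1L) 1 / en else 1 / (1 - en)
  }
  eta <- weighted_score_quantile(scores, w, w0, 1 - alpha)
  qn <- predict_quantile_bounds(models, newdata)
  data.frame(lo = qn$lo - eta, hi = qn$hi + eta, eta = eta)
}

xgb_mean_fit <- function(x, y, learner) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = learner$max_depth, eta = learner$eta,
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = learner$nrounds, verbose = 0L)
}

# stage-1 ITE bounds for `rows`: counterfactual interval for the unobserved
# arm combined with the observed factual outcome
stage1_ite_bounds <- function(rows_df, qb1, qb0, config, e_rows, e_calib,
                              calib, exposure) {
  y <- rows_df[[config$outcome]]
  t <- rows_df[[exposure]]
  L <- U <- numeric(nrow(rows_df))
  a1 <- config$alpha / 2
  if (any(t == 0)) {
    cf1 <- weighted_conformal_counterfactual(
      qb1, calib, rows_df[t == 0, , drop = FALSE], config,
      e_calib = e_calib, e_new = e_rows[t == 0], exposure = exposure,
      alpha = a1)
    L[t == 0] <- cf1$lo - y[t == 0]
    U[t == 0] <- cf1$hi - y[t == 0]
  }
  if (any(t == 1)) {
    cf0 <- weighted_conformal_counterfactual(
      qb0, calib, rows_df[t == 1, , drop = FALSE], config,
      e_calib = e_calib, e_new = e_rows[t == 1], exposure = exposure,
      alpha = a1)
    L[t == 1] <- y[t == 1] - cf0$hi
    U[t == 1] <- y[t == 1] - cf0$lo
  }
  data.frame(L = L, U = U)
}

#' Nested conformal ITE intervals
#'
#' The full two-stage procedure.  The cohort is split evenly (by
#' \code{split_fraction}) into a training and an evaluation part.  Within
#' the training part, one half fits the per-arm quantile regressors (at
#' miscoverage alpha/4 per tail of alpha/2) and a logistic propensity
#' model; the other half calibrates the weighted conformal counterfactual
#' intervals.  Each evaluation-part patient then receives stage-1 ITE
#' bounds from their factual outcome and counterfactual interval.  The
#' nested stage fits gradient-boosted regressions of the two bounds on the
#' covariates (one half of the evaluation part) and conformalizes them
#' (other half) at level 1 - alpha/2, yielding intervals defined for every
#' patient.  The two stage levels compose to an overall marginal guarantee
#' of at least 1 - alpha for a fresh patient.
#'
#' @param cohort cohort data frame.
#' @param config a \code{\link{conformal_config}}.
#' @param point optional per-patient point estimates of the ITE (e.g. the
#'   Dragonnet contrast \code{y1_hat - y0_hat}); defaults to the midpoint
#'   of the interval.  Points are clamped into their interval.
#' @param exposure treatment column name.
#' @param covariates covariate columns; defaults to everything except the
#'   treatment and the outcome columns.
#' @return an object of class \code{ite_intervals}: data frame with
#'   \code{patient_id}, \code{point}, \code{lo}, \code{hi}, \code{treated},
#'   with the stage-2 inflation \code{eta2} and the config as attributes.
#' @examples
#' sim <- generate_cohort(default_cohort_spec(n = 2000, seed = 11))
#' cfg <- conformal_config(outcome = "y_latent", seed = 11)
#' iv <- nested_ite_intervals(sim$cohort, cfg)
#' mean(iv$lo <= sim$truth$ite_latent & sim$truth$ite_latent <= iv$hi)
#' @export
nested_ite_intervals <- function(cohort, config = conformal_config(),
                                 point = NULL, exposure = "t",
                                 covariates = NULL) {
  stopifnot(inherits(config, "conformal_config"))
  if (is.null(covariates))
    covariates <- setdiff(names(cohort), c(exposure, "y", "y_latent"))
  n <- nrow(cohort)
  with_seed(config$seed, {
    idx <- sample.int(n)
    n_tr <- round(config$split_fraction * n)
    tr_idx <- idx[seq_len(n_tr)]
    ev_idx <- idx[-seq_len(n_tr)]
    fit_idx <- tr_idx[seq_len(floor(n_tr / 2))]
    cal_idx <- tr_idx[-seq_len(floor(n_tr / 2))]
    d_fit <- cohort[fit_idx, , drop = FALSE]
    d_cal <- cohort[cal_idx, , drop = FALSE]
    d_ev <- cohort[ev_idx, , drop = FALSE]
    a1 <- config$alpha / 2
    qb1 <- fit_quantile_bounds(d_fit, 1L, config, covariates = covariates,
                               exposure = exposure, alpha = a1)
    qb0 <- fit_quantile_bounds(d_fit, 0L, config, covariates = covariates,
                               exposure = exposure, alpha = a1)
    pfit <- stats::glm(stats::reformulate(covariates, response = exposure),
                       data = d_fit, family = stats::binomial())
    eta_of <- function(df) as.numeric(stats::predict(pfit, newdata = df,
                                                     type = "response"))
    b_ev <- stage1_ite_bounds(d_ev, qb1, qb0, config, eta_of(d_ev),
                              eta_of(d_cal), d_cal, exposure)
    # nested stage: bound regression on one half, conformalization on the
    # other
    m_ev <- nrow(d_ev)
    efit <- seq_len(floor(m_ev / 2))
    ecal <- setdiff(seq_len(m_ev), efit)
    x_ev <- as.matrix(d_ev[, covariates, drop = FALSE])
    fitL <- xgb_mean_fit(x_ev[efit, , drop = FALSE], b_ev$L[efit],
                         config$bound_learner)
    fitU <- xgb_mean_fit(x_ev[efit, , drop = FALSE], b_ev$U[efit],
                         config$bound_learner)
    x_all <- as.matrix(cohort[, covariates, drop = FALSE])
    lhat <- as.numeric(stats::predict(fitL, xgboost::xgb.DMatrix(x_all)))
    uhat <- as.numeric(stats::predict(fitU, xgboost::xgb.DMatrix(x_all)))
    s2 <- pmax(lhat[ev_idx][ecal] - b_ev$L[ecal],
               b_ev$U[ecal] - uhat[ev_idx][ecal])
    m2 <- length(s2)
    k <- ceiling((1 - config$alpha / 2) * (m2 + 1))
    eta2 <- if (k > m2) max(s2) else sort(s2)[k]
    lo <- pmin(lhat, uhat) - eta2
    hi <- pmax(lhat, uhat) + eta2
    if (all(cohort[[config$outcome]] %in% c(0, 1))) {
      lo <- pmax(lo, -1); hi <- pmin(hi, 1)
    }
    pt <- if (is.null(point)) (lo + hi) / 2 else pmin(pmax(point, lo), hi)
    out <- data.frame(patient_id = seq_len(n), point = pt, lo = lo,
                      hi = hi, treated = cohort[[exposure]])
    attr(out, "eta2") <- eta2
    attr(out, "config") <- config
    attr(out, "splits") <- list(train = sort(tr_idx), eval = sort(ev_idx))
    class(out) <- c("ite_intervals", "data.frame")
    out
  })
}

#' Stratified mean-ITE summary for untreated patients
#'
#' Restricts to patients not receiving the treatment and summarizes the
#' point ITEs within each combination of the stratifying risk factors
#' (default hypertension, diabetes, dyslipidemia).  Atrial fibrillation is
#' deliberately not allowed as a stratum (it is not an indication for
#' antiplatelet therapy) but remains a covariate upstream.
#'
#' @param intervals an \code{ite_intervals} object.
#' @param cohort the cohort the intervals refer to.
#' @param strata stratifying columns (must not include \code{af}).
#' @return an object of class \code{ite_summary}: data frame with
#'   \code{stratum}, \code{n}, \code{mean_ite}, \code{iqr_low},
#'   \code{iqr_high}; per-stratum point sets are kept in the
#'   \code{"points"} attribute for plotting.
#' @export
stratified_ite_summary <- function(intervals, cohort,
                                   strata = c("ht", "dm", "dlp")) {
  if ("af" %in% tolower(strata))
    stop("atrial fibrillation must not define an ITE stratum")
  stopifnot(all(strata %in% names(cohort)))
  untreated <- which(intervals$treated == 0)
  pts <- intervals$point[untreated]
  sub <- cohort[untreated, strata, drop = FALSE]
  label <- apply(sub, 1L, function(r) {
    on <- strata[r == 1]
    if (!length(on)) "none" else paste(on, collapse = "+")
  })
  combos <- apply(expand.grid(rep(list(c(0, 1)), length(strata))), 1L,
                  function(r) {
                    on <- strata[r == 1]
                    if (!length(on)) "none" else paste(on, collapse = "+")
                  })
  missing <- setdiff(combos, unique(label))
  if (length(missing))
    warning("empty stratum combination(s) omitted: ",
            paste(missing, collapse = ", "))
  groups <- split(pts, label)
  out <- data.frame(
    stratum = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_ite = vapply(groups, mean, numeric(1)),
    iqr_low = vapply(groups, function(v)
      stats::quantile(v, 0.25, names = FALSE), numeric(1)),
    iqr_high = vapply(groups, function(v)
      stats::quantile(v, 0.75, names = FALSE), numeric(1)),
    row.names = NULL)
  out <- out[order(out$mean_ite), ]
  attr(out, "points") <- groups
  class(out) <- c("ite_summary", "data.frame")
  out
}

#' @export
plot.ite_summary <- function(x, ...) {
  pts <- attr(x, "points")[x$stratum]
  graphics::boxplot(pts, las = 2,
                    ylab = "individual treatment effect",
                    main = "Mean ITE of untreated patients by risk stratum",
                    ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Write ITE tables
#'
#' Per-patient intervals as \code{patient_id,point,lo,hi,treated} and the
#' stratified summary as \code{stratum,n,mean_ite,iqr_low,iqr_high}.
#'
#' @param intervals an \code{ite_intervals} object.
#' @param summary an \code{ite_summary} object.
#' @param path file path.
#' @export
export_ite_intervals <- function(intervals, path) {
  write_csv17(as.data.frame(intervals), path)
}

#' @rdname export_ite_intervals
#' @export
export_ite_summary <- function(summary, path) {
  write_csv17(as.data.frame(summary), path)
}
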