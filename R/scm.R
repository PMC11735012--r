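# Structural-causal-model cohort simulator.
#
# Nodes follow the clinical diagram in stroke_dag(): exogenous age, sex, BMI;
# binary comorbidities dm, dlp, ht, ckd, af generated by logistic structural
# equations in topological order; antiplatelet treatment t assigned with
# confounding by indication; binary stroke outcome y (plus a continuous
# latent-risk outcome) with treatment-effect heterogeneity in the dm and ht
# strata.  Continuous parents enter every equation standardized:
# (age - 62)/12 and (bmi - 25)/4.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

scm_endogenous <- function() c("dm", "dlp", "ht", "ckd", "af", "t", "y")

# structural parents per endogenous node (t -> y handled by treatment_effect)
scm_parent_sets <- function() {
  list(dm  = c("age", "bmi"),
       dlp = "age",
       ht  = c("age", "dm", "dlp"),
       ckd = c("age", "dm", "ht"),
       af  = c("age", "ht"),
       t   = c("age", "ht", "dm", "dlp"),
       y   = c("age", "bmi", "dm", "dlp", "ht", "ckd", "af"))
}

#' Specify a synthetic stroke cohort
#'
#' Bundles every parameter of the structural causal model: sample size, RNG
#' seed, exogenous covariate distributions, per-edge log-odds coefficients,
#' per-node intercepts, the treatment-assignment model and the heterogeneous
#' treatment effect on the outcome log-odds.
#'
#' @param n number of patients (>= 1).
#' @param seed integer RNG seed; identical specs reproduce identical cohorts.
#' @param coefficients named list, one entry per endogenous node, each a
#'   named numeric vector of log-odds coefficients keyed by parent node.
#'   Only edges present in \code{\link{stroke_dag}} are allowed.
#' @param intercepts named numeric vector of log-odds intercepts for
#'   \code{dm, dlp, ht, ckd, af, t, y}.
#' @param treatment_effect numeric vector \code{c(base, dm, ht)}: the
#'   treatment log-odds effect on stroke is \code{base + dm_i * dm + ht_i *
#'   ht}, so a negative \code{base} with negative modifiers concentrates the
#'   benefit in the dm and dm+ht strata.
#' @param exogenous list with \code{age_mean, age_sd, age_min, sex_p,
#'   bmi_mean, bmi_sd}; age is truncated below at \code{age_min} (cohort
#'   eligibility: adults only).
#' @param latent_sd standard deviation of the Gaussian noise added to the
#'   outcome linear predictor to form the continuous latent-risk outcome
#'   \code{y_latent}.
#' @return an object of class \code{cohort_spec}.
#' @seealso \code{\link{default_cohort_spec}}, \code{\link{generate_cohort}}
#' @export
cohort_spec <- function(n, seed, coefficients, intercepts,
                        treatment_effect = c(base = 0, dm = 0, ht = 0),
                        exogenous = list(age_mean = 62, age_sd = 12,
                                         age_min = 18, sex_p = 0.5,
                                         bmi_mean = 25, bmi_sd = 4),
                        latent_sd = 0.5) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  par_sets <- scm_parent_sets()
  endo <- scm_endogenous()
  if (!all(names(coefficients) %in% endo))
    stop("coefficients for unknown node(s): ",
         paste(setdiff(names(coefficients), endo), collapse = ", "))
  for (v in names(coefficients)) {
    bad <- setdiff(names(coefficients[[v]]), par_sets[[v]])
    if (length(bad))
      stop("coefficient(s) on absent edge(s) into '", v, "': ",
           paste(bad, collapse = ", "))
  }
  if (!all(endo %in% names(intercepts)))
    stop("intercepts must name every endogenous node")
  te <- c(base = 0, dm = 0, ht = 0)
  te[names(treatment_effect)] <- treatment_effect
  if (!is.numeric(latent_sd) || latent_sd <= 0)
    stop("latent_sd must be positive")
  structure(list(n = n, seed = as.integer(seed),
                 coefficients = coefficients,
                 intercepts = intercepts[endo],
                 treatment_effect = te,
                 exogenous = exogenous,
                 latent_sd = latent_sd),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec: n =", x$n, ", seed =", x$seed, "\n")
  cat("  treatment effect (log-odds): base", x$treatment_effect[["base"]],
      "+", x$treatment_effect[["dm"]], "* dm +",
      x$treatment_effect[["ht"]], "* ht\n")
  invisible(x)
}

#' Default calibrated cohort specification
#'
#' The committed default parameterization of the synthetic stroke cohort.
#' Coefficients and intercepts were fixed by a one-time calibration of the
#' structural model against the target marginal stroke incidence (3.5\%) and
#' the stratified stroke rates (13\% vs 2\% by atrial fibrillation, 4\% vs
#' 1\% by hypertension, 4\% vs 3\% by diabetes and by dyslipidemia), with
#' risk-factor prevalences consistent with those rates (af about 14\%, ht
#' about 83\%, dm and dlp about 50\%).  Treatment assignment depends on ht,
#' dm, dlp and age, with propensities bounded inside (0.05, 0.95) by
#' construction; the treatment effect is protective and strongest for
#' patients with diabetes, alone or with hypertension.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param randomized if \code{TRUE}, treatment is assigned by a fair coin
#'   independent of covariates (a randomized-trial variant of the same
#'   outcome model), useful for estimator benchmarking.
#' @param latent_sd noise level of the continuous latent-risk outcome.
#' @return a \code{\link{cohort_spec}}.
#' @export
default_cohort_spec <- function(n = 100000, seed = 20260927,
                                randomized = FALSE, latent_sd = 0.5) {
  coefficients <- list(
    dm  = c(age = 0.20, bmi = 0.40),
    dlp = c(age = 0.50),
    ht  = c(age = 0.70, dm = 0.80, dlp = 0.30),
    ckd = c(age = 0.50, dm = 0.60, ht = 0.70),
    af  = c(age = 0.80, ht = 0.90),
    t   = c(age = 0.40, ht = 0.80, dm = 0.20, dlp = 0.20),
    y   = c(age = 0.550, bmi = 0.100, dm = 0.442, dlp = -0.052,
            ht = 0.840, ckd = 0.300, af = 1.615))
  intercepts <- c(dm = 0.000, dlp = -0.003, ht = 1.296, ckd = -2.787,
                  af = -2.884, t = -1.200, y = -4.703)
  if (randomized) {
    coefficients$t <- c(age = 0, ht = 0, dm = 0, dlp = 0)
    intercepts[["t"]] <- 0
  }
  cohort_spec(n = n, seed = seed, coefficients = coefficients,
              intercepts = intercepts,
              treatment_effect = c(base = -0.10, dm = -1.00, ht = -0.15),
              latent_sd = latent_sd)
}

#' Null cohort specification
#'
#' A structural model with every edge coefficient and treatment effect set
#' to zero and all node probabilities equal to \code{p}: no confounding, no
#' causal effects.  Used as a negative control.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param p common marginal probability of every binary node.
#' @return a \code{\link{cohort_spec}}.
#' @export
null_cohort_spec <- function(n = 10000, seed = 1, p = 0.5) {
  zero <- lapply(scm_parent_sets(), function(par)
    stats::setNames(rep(0, length(par)), par))
  b0 <- stats::qlogis(p)
  cohort_spec(n = n, seed = seed, coefficients = zero,
              intercepts = stats::setNames(rep(b0, 7), scm_endogenous()))
}

node_lp <- function(spec, node, data) {
  lp <- rep(spec$intercepts[[node]], nrow(data))
  co <- spec$coefficients[[node]]
  ex <- spec$exogenous
  for (p in names(co)) {
    val <- switch(p,
                  age = (data$age - ex$age_mean) / ex$age_sd,
                  bmi = (data$bmi - ex$bmi_mean) / ex$bmi_sd,
                  data[[p]])
    lp <- lp + co[[p]] * val
  }
  lp
}

outcome_lp <- function(spec, data, t) {
  tau <- spec$treatment_effect[["base"]] +
    spec$treatment_effect[["dm"]] * data$dm +
    spec$treatment_effect[["ht"]] * data$ht
  node_lp(spec, "y", data) + tau * t
}

draw_exogenous <- function(spec, n) {
  ex <- spec$exogenous
  p_lo <- stats::pnorm(ex$age_min, ex$age_mean, ex$age_sd)
  age <- stats::qnorm(stats::runif(n, p_lo, 1), ex$age_mean, ex$age_sd)
  data.frame(age = age,
             sex = as.numeric(stats::runif(n) < ex$sex_p),
             bmi = stats::rnorm(n, ex$bmi_mean, ex$bmi_sd))
}

# propagate endogenous nodes in topological order; `u` holds one uniform per
# node and row so that counterfactual worlds can be coupled; `intervene`
# fixes named nodes to constants
propagate <- function(spec, data, u, intervene = list()) {
  for (v in c("dm", "dlp", "ht", "ckd", "af", "t")) {
    if (v %in% names(intervene)) {
      data[[v]] <- rep(intervene[[v]], nrow(data))
    } else {
      data[[v]] <- as.numeric(u[, v] < stats::plogis(node_lp(spec, v, data)))
    }
  }
  data
}

#' Generate a synthetic cohort with exact ground truth
#'
#' Samples a cohort from the structural causal model in topological order
#' (age, sex, bmi; dm, dlp; ht; ckd, af; t; y) and returns, alongside the
#' observed data, the per-patient potential-outcome probabilities computed
#' analytically from the outcome equation at t = 1 and t = 0.  Because
#' treatment has no descendants other than the outcome, these plug-in
#' potential outcomes are exact.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a list of class \code{synthetic_cohort} with elements:
#'   \describe{
#'     \item{cohort}{data frame with columns \code{age, sex, bmi, ckd, af,
#'       ht, dm, dlp, t, y, y_latent}; \code{y} is the binary stroke
#'       outcome, \code{y_latent} the continuous latent risk (outcome
#'       log-odds plus Gaussian noise).}
#'     \item{truth}{data frame with \code{p1, p0, ite} (probability-scale
#'       potential outcomes and their difference) and \code{mu1, mu0,
#'       ite_latent} (latent scale; \code{ite_latent} is the true treatment
#'       effect for \code{y_latent}).}
#'     \item{spec}{the input specification.}
#'   }
#' @examples
#' sim <- generate_cohort(default_cohort_spec(n = 2000, seed = 7))
#' mean(sim$cohort$y)          # close to the 3.5% target incidence
#' mean(sim$truth$ite)         # true average treatment effect
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    data <- draw_exogenous(spec, n)
    u <- matrix(stats::runif(n * 6), n, 6,
                dimnames = list(NULL, c("dm", "dlp", "ht", "ckd", "af", "t")))
    data <- propagate(spec, data, u)
    mu1 <- outcome_lp(spec, data, 1)
    mu0 <- outcome_lp(spec, data, 0)
    p1 <- stats::plogis(mu1)
    p0 <- stats::plogis(mu0)
    mu_obs <- ifelse(data$t == 1, mu1, mu0)
    data$y <- as.numeric(stats::runif(n) < stats::plogis(mu_obs))
    data$y_latent <- mu_obs + stats::rnorm(n, 0, spec$latent_sd)
    cohort <- data[, c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp",
                       "t", "y", "y_latent")]
    truth <- data.frame(p1 = p1, p0 = p0, ite = p1 - p0,
                        mu1 = mu1, mu0 = mu0, ite_latent = mu1 - mu0)
    structure(list(cohort = cohort, truth = truth, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: n =", nrow(x$cohort),
      "| incidence", sprintf("%.3f", mean(x$cohort$y)),
      "| treated", sprintf("%.3f", mean(x$cohort$t)),
      "| mean true ITE", sprintf("%+.4f", mean(x$truth$ite)), "\n")
  invisible(x)
}

#' True causal effect of an exposure by forced-exposure simulation
#'
#' Computes the ground-truth average causal risk difference and risk ratio
#' of a binary exposure on stroke by two-world Monte-Carlo simulation: the
#' exposure is forced to 1 for everyone and to 0 for everyone, its
#' descendants are re-propagated through the structural equations (the two
#' worlds share all exogenous draws and structural noise, i.e. are coupled),
#' and the mean outcome probabilities are contrasted.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param exposure one of \code{"af", "ht", "dm", "dlp", "t"}.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the simulation (defaults to \code{spec$seed}).
#' @param condition optional named list restricting the population, e.g.
#'   \code{list(dm = 1)} for the effect within the diabetic stratum.
#'   Conditioning values are taken from the natural (unintervened) world and
#'   must not be descendants of the exposure.
#' @return a list with \code{risk_difference}, \code{risk_ratio},
#'   \code{se_rd}, \code{se_rr} and \code{n} (rows retained after
#'   conditioning).
#' @export
ground_truth_effects <- function(spec, exposure, n_mc = 200000,
                                 seed = spec$seed, condition = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  exposure <- tolower(exposure)
  if (!exposure %in% c("af", "ht", "dm", "dlp", "t"))
    stop("unknown exposure '", exposure, "'")
  dag <- stroke_dag()
  if (!is.null(condition)) {
    bad <- intersect(names(condition), descendants(dag, exposure))
    if (length(bad))
      stop("conditioning on descendant(s) of the exposure: ",
           paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    data <- draw_exogenous(spec, n_mc)
    u <- matrix(stats::runif(n_mc * 6), n_mc, 6,
                dimnames = list(NULL, c("dm", "dlp", "ht", "ckd", "af", "t")))
    natural <- propagate(spec, data, u)
    w1 <- propagate(spec, data, u, intervene = stats::setNames(list(1), exposure))
    w0 <- propagate(spec, data, u, intervene = stats::setNames(list(0), exposure))
    py <- function(w) stats::plogis(outcome_lp(spec, w, w$t))
    py1 <- py(w1); py0 <- py(w0)
    keep <- rep(TRUE, n_mc)
    for (v in names(condition)) keep <- keep & natural[[v]] == condition[[v]]
    py1 <- py1[keep]; py0 <- py0[keep]
    m <- sum(keep)
    rd <- mean(py1) - mean(py0)
    rr <- mean(py1) / mean(py0)
    se_rd <- stats::sd(py1 - py0) / sqrt(m)
    # delta method for the ratio of coupled means
    v11 <- stats::var(py1) / m; v00 <- stats::var(py0) / m
    c10 <- stats::cov(py1, py0) / m
    se_rr <- rr * sqrt(v11 / mean(py1)^2 + v00 / mean(py0)^2 -
                         2 * c10 / (mean(py1) * mean(py0)))
    list(risk_difference = rd, risk_ratio = rr,
         se_rd = se_rd, se_rr = se_rr, n = m)
  })
}

#' Read and write cohort CSV files
#'
#' The on-disk schema is a comma-separated UTF-8 file with header
#' \code{age,sex,bmi,ckd,af,ht,dm,dlp,t,y} (an extra \code{y_latent} column
#' is written when present).  Numeric values are written with 17 significant
#' digits so that a write/read round trip reproduces the doubles exactly.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return \code{read_cohort} returns the cohort data frame;
#'   \code{export_cohort} returns \code{path} invisibly.
#' @export
export_cohort <- function(cohort, path) {
  cols <- c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp", "t", "y")
  if ("y_latent" %in% names(cohort)) cols <- c(cols, "y_latent")
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) stop("cohort lacks column(s): ",
                            paste(missing, collapse = ", "))
  write_csv17(cohort[, cols, drop = FALSE], path)
}

#' @rdname export_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path)
  need <- c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp", "t", "y")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("file lacks column(s): ",
                            paste(missing, collapse = ", "))
  x[] <- lapply(x, as.numeric)   # indicator columns are numeric 0/1
  x
}

#' Export per-patient ground truth
#'
#' Writes the potential-outcome table with header \code{p1,p0,ite} (latent
#' columns appended when present).
#'
#' @param truth the \code{truth} element of a \code{\link{generate_cohort}}
#'   result.
#' @param path file path.
#' @export
export_ground_truth <- function(truth, path) {
  cols <- intersect(c("p1", "p0", "ite", "mu1", "mu0", "ite_latent"),
                    names(truth))
  write_csv17(truth[, cols, drop = FALSE], path)
}

# CSV writer with exact double round-trip (17 significant digits)
write_csv17 <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
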