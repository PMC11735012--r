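# Natural direct and indirect effects via the mediational g-formula.
#
# Binary mediators only.  The joint mediator distribution given exposure
# and covariates is factorized along the causal diagram: mediators are
# processed in topological order and each mediator model conditions on the
# exposure, the adjustment covariates and every mediator that precedes it.
# Effects are standardized over the empirical covariate distribution, so
# the decomposition NDE + NIE = total effect is exact by construction.

#' Natural direct and indirect effects
#'
#' Computes, for a binary exposure \code{x} with binary mediators \code{M}:
#' \deqn{NDE = E_Z \sum_m [E(Y|x=1,m,Z) - E(Y|x=0,m,Z)] P(m|x=0,Z)}
#' \deqn{NIE = E_Z \sum_m E(Y|x=1,m,Z) [P(m|x=1,Z) - P(m|x=0,Z)]}
#' with the total effect \code{NDE + NIE}.  The outcome model is a logistic
#' regression of the outcome on exposure, mediators and adjustment
#' covariates; each mediator model is a logistic regression on exposure,
#' adjustment covariates and upstream mediators.
#'
#' @param cohort cohort data frame.
#' @param exposure binary exposure column name.
#' @param mediators character vector of binary mediator columns; by default
#'   derived from \code{dag} as the descendants of the exposure that are
#'   ancestors of the outcome, excluding the treatment node.
#' @param adjustment covariate columns; by default the backdoor adjustment
#'   set for the exposure in \code{dag}.
#' @param outcome outcome column (default \code{"y"}).
#' @param dag a \code{\link{causal_dag}} used for the defaults.
#' @param ci if \code{TRUE}, adds percentile-bootstrap 95\% intervals.
#' @param B,seed bootstrap replicates and seed.
#' @param saturated if \code{TRUE}, the outcome and mediator models include
#'   all interactions among exposure and mediators (with no adjustment
#'   covariates this makes the fits equal the empirical conditional
#'   frequencies, so the g-formula reduces to exact enumeration over the
#'   observed tables).
#' @return object of class \code{mediation_effects}: list with \code{nde},
#'   \code{nie}, \code{total}, the mediator/adjustment sets, and (with
#'   \code{ci}) interval bounds \code{ci} (matrix).
#' @examples
#' sim <- generate_cohort(default_cohort_spec(n = 5000, seed = 3))
#' mediation_effects(sim$cohort, "ht")
#' @export
mediation_effects <- function(cohort, exposure, mediators = NULL,
                              adjustment = NULL, outcome = "y",
                              dag = stroke_dag(), ci = FALSE, B = 200L,
                              seed = 1L, saturated = FALSE) {
  if (is.null(mediators)) {
    med <- intersect(descendants(dag, exposure), ancestors(dag, outcome))
    mediators <- setdiff(med, c("t", outcome))
    mediators <- intersect(topological_sort(dag), mediators)
  }
  if (!length(mediators)) stop("no mediators between '", exposure,
                               "' and '", outcome, "'")
  if (is.null(adjustment))
    adjustment <- backdoor_adjustment_set(dag, exposure, outcome)
  for (m in mediators)
    if (!all(cohort[[m]] %in% c(0, 1)))
      stop("mediator '", m, "' is not binary; only binary mediators are supported")
  check_binary(cohort[[exposure]], "exposure")
  # keep mediators in topological order so each model conditions on its
  # upstream mediators only
  ord <- intersect(topological_sort(dag), mediators)
  if (length(ord) == length(mediators)) mediators <- ord

  point_fn <- function(data) {
    join <- if (saturated) "*" else "+"
    out_f <- stats::as.formula(paste(
      outcome, "~", paste(c(paste(c(exposure, mediators), collapse = join),
                            adjustment), collapse = "+")))
    fam <- if (all(data[[outcome]] %in% c(0, 1))) stats::binomial()
    else stats::gaussian()
    out_fit <- stats::glm(out_f, data = data, family = fam)
    med_fits <- lapply(seq_along(mediators), function(j) {
      up <- c(exposure, if (j > 1L) mediators[seq_len(j - 1L)])
      f <- stats::as.formula(paste(
        mediators[j], "~", paste(c(paste(up, collapse = join), adjustment),
                                 collapse = "+")))
      stats::glm(f, data = data, family = stats::binomial())
    })
    configs <- expand.grid(rep(list(c(0, 1)), length(mediators)))
    names(configs) <- mediators
    n <- nrow(data)
    # per-patient E(Y|x,m,Z) and P(m|x,Z) for each mediator configuration
    ey <- function(xval, mrow) {
      nd <- data
      nd[[exposure]] <- xval
      for (m in mediators) nd[[m]] <- mrow[[m]]
      stats::predict(out_fit, newdata = nd, type = "response")
    }
    pm <- function(xval, mrow) {
      nd <- data
      nd[[exposure]] <- xval
      p <- rep(1, n)
      for (j in seq_along(mediators)) {
        pj <- stats::predict(med_fits[[j]], newdata = nd, type = "response")
        mj <- mrow[[mediators[j]]]
        p <- p * (pj * mj + (1 - pj) * (1 - mj))
        nd[[mediators[j]]] <- mj
      }
      p
    }
    nde <- nie <- rep(0, n)
    for (r in seq_len(nrow(configs))) {
      mrow <- configs[r, , drop = FALSE]
      ey1 <- ey(1, mrow); ey0 <- ey(0, mrow)
      pm0 <- pm(0, mrow); pm1 <- pm(1, mrow)
      nde <- nde + (ey1 - ey0) * pm0
      nie <- nie + ey1 * (pm1 - pm0)
    }
    c(nde = mean(nde), nie = mean(nie), total = mean(nde) + mean(nie))
  }
  est <- point_fn(cohort)
  res <- structure(list(nde = est[["nde"]], nie = est[["nie"]],
                        total = est[["total"]], exposure = exposure,
                        mediators = mediators, adjustment = adjustment),
                   class = "mediation_effects")
  if (ci) {
    cis <- sapply(c("nde", "nie", "total"), function(k)
      bootstrap_ci(function(d) point_fn(d)[[k]], cohort, B = B, seed = seed))
    res$ci <- cis
  }
  res
}

#' @export
print.mediation_effects <- function(x, ...) {
  cat(sprintf("mediation_effects for '%s' via {%s}:\n", x$exposure,
              paste(x$mediators, collapse = ", ")))
  cat(sprintf("  NDE   %+0.5f\n  NIE   %+0.5f\n  total %+0.5f\n",
              x$nde, x$nie, x$total))
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CIs:\n")
    for (k in colnames(x$ci))
      cat(sprintf("    %-5s %+0.5f to %+0.5f\n", k, x$ci["ci_low", k],
                  x$ci["ci_high", k]))
  }
  invisible(x)
}
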