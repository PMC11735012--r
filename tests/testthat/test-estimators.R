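test_that("propensity scores recover known assignment mechanisms", {
  set.seed(11)
  n <- 4000
  # fair coin, independent of covariates
  d <- data.frame(x = rnorm(n), t = rbinom(n, 1, 0.5))
  ps <- fit_propensity(d, "t", "x")
  expect_true(all(abs(ps$e - 0.5) < 0.05))
  # exposure follows a binary covariate 90% of the time: fitted scores must
  # match the empirical 2x2 conditional frequencies
  d2 <- data.frame(x = rbinom(n, 1, 0.5))
  d2$t <- ifelse(rbinom(n, 1, 0.9) == 1, d2$x, 1 - d2$x)
  ps2 <- fit_propensity(d2, "t", "x")
  for (xv in 0:1) {
    emp <- mean(d2$t[d2$x == xv])
    expect_equal(unique(round(ps2$e[d2$x == xv], 10)), round(emp, 10),
                 tolerance = 1e-6)
  }
  expect_error(fit_propensity(data.frame(x = 1:5, t = rep(1, 5)), "t", "x"),
               "constant")
})

test_that("propensity scores on the synthetic cohort are decile-calibrated", {
  d <- cached_sim(20000, 21)$cohort
  ps <- fit_propensity(d, "t", c("age", "ht", "dm", "dlp"))
  dec <- cut(ps$e, stats::quantile(ps$e, 0:10 / 10), include.lowest = TRUE)
  gap <- abs(tapply(ps$e, dec, mean) - tapply(d$t, dec, mean))
  expect_true(all(gap < 0.05))
})

test_that("propensity stratification reduces to known closed forms", {
  set.seed(31)
  n <- 2000
  # homogeneous propensity -> single stratum -> plain difference in means
  d <- data.frame(x = rnorm(n), t = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, 0.2 + 0.3 * d$t)
  est <- sps_ate(d, "t", character(0))
  expect_equal(est$point, mean(d$y[d$t == 1]) - mean(d$y[d$t == 0]),
               tolerance = 1e-12)
  # two hand-built strata keyed by a binary covariate
  d2 <- data.frame(x = rep(c(0, 1), each = 400))
  set.seed(5)
  d2$t <- rbinom(800, 1, ifelse(d2$x == 1, 0.7, 0.3))
  d2$y <- rbinom(800, 1, 0.1 + 0.2 * d2$x + 0.15 * d2$t)
  hand <- sum(vapply(0:1, function(xv) {
    idx <- d2$x == xv
    w <- mean(idx)
    w * (mean(d2$y[idx & d2$t == 1]) - mean(d2$y[idx & d2$t == 0]))
  }, numeric(1)))
  est2 <- sps_ate(d2, "t", "x")
  expect_equal(est2$point, hand, tolerance = 1e-10)
})

test_that("IPW reduces to the arm contrast under known equal propensities", {
  set.seed(41)
  n <- 1000
  d <- data.frame(x = rnorm(n), t = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-1 + 0.5 * d$x + 0.3 * d$t))
  half <- structure(list(e = rep(0.5, n)), class = "propensity_scores")
  est <- ipw_ate(d, "t", "x", propensity = half)
  expect_equal(est$point, 2 * mean(d$t * d$y) - 2 * mean((1 - d$t) * d$y),
               tolerance = 1e-12)
})

test_that("IPW equals the hand-summed Horvitz-Thompson contrast on a toy table", {
  d <- data.frame(t = c(1, 1, 1, 0, 0, 0, 1, 0),
                  y = c(1, 0, 1, 1, 0, 0, 1, 1))
  e <- c(0.8, 0.6, 0.5, 0.4, 0.3, 0.5, 0.7, 0.2)
  ps <- structure(list(e = e), class = "propensity_scores")
  d$x <- 0  # adjustment unused when propensities are supplied
  hand <- mean(d$t * d$y / e) - mean((1 - d$t) * d$y / (1 - e))
  est <- suppressWarnings(ipw_ate(d, "t", "x", propensity = ps))
  expect_equal(est$point, hand, tolerance = 1e-12)
})

test_that("IPW with constant propensities is invariant to covariate permutation", {
  d <- cached_sim(5000, 21)$cohort
  half <- structure(list(e = rep(0.5, nrow(d))),
                    class = "propensity_scores")
  a <- ipw_ate(d, "t", c("age", "bmi"), propensity = half)
  d_perm <- d
  set.seed(1)
  perm <- sample.int(nrow(d))
  d_perm$age <- d$age[perm]
  d_perm$bmi <- d$bmi[perm]
  b <- ipw_ate(d_perm, "t", c("age", "bmi"), propensity = half)
  expect_identical(a$point, b$point)
})

test_that("PS estimators recover the true effect where the naive contrast fails", {
  sim <- cached_sim(20000, 21)
  d <- sim$cohort
  truth <- mean(sim$truth$ite)
  adj <- c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp")
  for (fn in list(sps_ate, ipw_ate, dre_ate)) {
    est <- fn(d, "t", adj)
    expect_lt(abs(est$point - truth), 3 * est$se, label = est$estimator)
  }
  naive <- naive_difference(d, "t")
  expect_gt(abs(naive$point - truth), 3 * naive$se)
})

test_that("estimators agree with the naive difference on randomized data", {
  sim <- cached_sim(20000, 22, randomized = TRUE)
  d <- sim$cohort
  adj <- c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp")
  naive <- naive_difference(d, "t")
  for (fn in list(sps_ate, ipw_ate, dre_ate)) {
    est <- fn(d, "t", adj)
    expect_lt(abs(est$point - naive$point), 3 * sqrt(est$se^2 + naive$se^2),
              label = est$estimator)
  }
})

test_that("augmented IPW evaluates its score exactly at supplied nuisances", {
  sim <- cached_sim(5000, 21)
  d <- sim$cohort
  m1 <- sim$truth$p1; m0 <- sim$truth$p0
  e <- fit_propensity(d, "t", c("age", "ht", "dm", "dlp"))$e
  est <- dre_ate(d, "t", character(0), m1 = m1, m0 = m0, e = e)
  psi <- m1 - m0 + d$t * (d$y - m1) / e - (1 - d$t) * (d$y - m0) / (1 - e)
  expect_equal(est$point, mean(psi), tolerance = 1e-12)
  # with oracle nuisances the estimate sits near the plug-in mean ITE
  expect_lt(abs(est$point - mean(sim$truth$ite)), 3 * est$se)
})

test_that("doubly robust estimation survives single-nuisance misspecification", {
  sim <- cached_sim(30000, 23)
  d <- sim$cohort
  truth <- mean(sim$truth$ite)
  adj <- c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp")
  # arm 1: outcome model destroyed (intercept-only), propensity fitted
  bad_m <- rep(mean(d$y), nrow(d))
  est1 <- dre_ate(d, "t", adj, m1 = bad_m, m0 = bad_m)
  expect_lt(abs(est1$point - truth), 3 * est1$se)
  # arm 2: propensity destroyed (marginal rate), oracle outcome models
  bad_e <- rep(mean(d$t), nrow(d))
  est2 <- dre_ate(d, "t", adj, m1 = sim$truth$p1, m0 = sim$truth$p0,
                  e = bad_e)
  expect_lt(abs(est2$point - truth), 3 * est2$se)
  # plain IPW with the same destroyed propensity is biased
  ps_bad <- structure(list(e = bad_e), class = "propensity_scores")
  ipw_bad <- ipw_ate(d, "t", adj, propensity = ps_bad)
  expect_gt(abs(ipw_bad$point - truth), 3 * ipw_bad$se)
  # plug-in with the destroyed outcome model is biased too
  plugin_bad <- mean(bad_m) - mean(bad_m)
  expect_gt(abs(plugin_bad - truth), 0.01)
})

test_that("the logistic odds-ratio baseline matches closed forms", {
  # 2x2 table with counts (20, 10, 10, 20): OR = (20*20)/(10*10) = 4
  d <- data.frame(t = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
                  y = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
  est <- logistic_or_baseline(d, "t", character(0))
  expect_equal(est$point, 4, tolerance = 1e-6)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # brute-force likelihood maximization over a parameter grid
  grid <- expand.grid(b0 = seq(-1.5, 1.5, by = 0.002),
                      b1 = seq(0.5, 2.5, by = 0.002))
  ll <- with(grid, {
    p <- plogis(b0 + b1 * 1)
    q <- plogis(b0)
    20 * log(p) + 10 * log(1 - p) + 10 * log(q) + 20 * log(1 - q)
  })
  best <- grid[which.max(ll), ]
  expect_equal(log(est$point), best$b1, tolerance = 0.005)
  # null cohort: no association
  dn <- generate_cohort(null_cohort_spec(n = 20000, seed = 6))$cohort
  est_null <- logistic_or_baseline(dn, "af", c("age", "ht"))
  expect_equal(est_null$point, 1, tolerance = 0.1)
})

test_that("bootstrap intervals are reproducible and degenerate correctly", {
  d <- data.frame(t = rep(0:1, 50), y = rep(1, 100), x = rnorm(100))
  fn <- function(data) mean(data$y)
  ci <- bootstrap_ci(fn, d, B = 100, seed = 3)
  expect_identical(unname(ci[1]), 1)
  expect_identical(unname(ci[2]), 1)
  d2 <- cached_sim(2000, 21)$cohort
  fn2 <- function(data) naive_difference(data, "t")$point
  a <- bootstrap_ci(fn2, d2, B = 150, seed = 9)
  b <- bootstrap_ci(fn2, d2, B = 150, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_ci(fn2, d2, B = 50, seed = 1), "at least 100")
})

test_that("bootstrap IPW intervals achieve near-nominal coverage", {
  spec0 <- default_cohort_spec(n = 400, seed = 1)
  truth <- ground_truth_effects(spec0, "t", n_mc = 200000,
                                seed = 2)$risk_difference
  adj <- c("age", "ht", "dm", "dlp")
  covered <- vapply(1:100, function(r) {
    sim <- generate_cohort(default_cohort_spec(n = 400, seed = 5000 + r))
    est <- tryCatch(
      suppressWarnings(ipw_ate(sim$cohort, "t", adj, ci = TRUE, B = 120,
                               seed = r)),
      error = function(e) NULL)
    if (is.null(est)) return(NA)
    est$ci_low <= truth && truth <= est$ci_high
  }, logical(1))
  cov <- mean(covered, na.rm = TRUE)
  expect_gt(cov, 0.86)   # 95% nominal, small-n percentile bootstrap
})
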