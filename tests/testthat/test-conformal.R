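test_that("quantile regressors recover Gaussian conditional quantiles", {
  set.seed(20)
  n <- 5000
  d <- data.frame(x1 = runif(n, -2, 2), x2 = rnorm(n))
  d$t <- 1
  sigma <- 0.6
  d$yc <- 1.5 * d$x1 + rnorm(n, 0, sigma)
  cfg <- conformal_config(alpha = 0.05, outcome = "yc")
  qb <- fit_quantile_bounds(d, 1L, cfg, covariates = c("x1", "x2"))
  q <- predict_quantile_bounds(qb, d)
  gap_true <- 2 * qnorm(0.975) * sigma
  expect_equal(mean(q$hi - q$lo), gap_true, tolerance = 0.2 * gap_true)
  # fitted quantiles beat the constant empirical quantile in pinball loss
  expect_lt(pinball(d$yc, predict_quantile_bounds(qb, d)$hi, 0.975),
            pinball(d$yc, rep(quantile(d$yc, 0.975), n), 0.975))
  expect_lt(pinball(d$yc, q$lo, 0.025),
            pinball(d$yc, rep(quantile(d$yc, 0.025), n), 0.025))
})

test_that("zero-noise outcomes collapse the quantile band onto the mean surface", {
  set.seed(21)
  n <- 3000
  d <- data.frame(x1 = runif(n, -2, 2), x2 = rnorm(n), t = 1)
  d$yc <- 2 * d$x1
  cfg <- conformal_config(outcome = "yc")
  qb <- fit_quantile_bounds(d, 1L, cfg, covariates = c("x1", "x2"))
  q <- predict_quantile_bounds(qb, d)
  expect_lt(mean(q$hi - q$lo), 0.15)
  expect_lt(mean(abs((q$hi + q$lo) / 2 - d$yc)), 0.15)
  expect_error(fit_quantile_bounds(d[d$t == 0, ], 1L, cfg), "absent")
})

test_that("the weighted score quantile behaves at its limits", {
  wq <- strokeITE:::weighted_score_quantile
  # all-equal scores: the inflation is that common score whatever the weights
  s <- rep(0.7, 50)
  expect_equal(wq(s, runif(50, 0.5, 5), c(1, 10, 100), 0.95),
               rep(0.7, 3), tolerance = 1e-12)
  # near-1 miscoverage keeps only a tiny correction
  s2 <- sort(runif(200))
  expect_lte(wq(s2, rep(1, 200), 1, 1 - 0.99), quantile(s2, 0.05))
  # uniform weights reduce to the usual (1 - alpha)(1 + 1/m) empirical rank
  m <- 99
  s3 <- seq_len(m) / m
  k <- ceiling(0.95 * (m + 1))
  expect_equal(wq(s3, rep(1, m), 1, 0.95), s3[k], tolerance = 1e-12)
})

test_that("uniform-weight split-CQR covers exchangeable counterfactuals", {
  covered <- numeric(30)
  for (r in 1:30) {
    set.seed(300 + r)
    n <- 600
    d <- data.frame(x1 = runif(n, -2, 2), x2 = rnorm(n))
    d$t <- rbinom(n, 1, 0.5)
    mu <- function(x1) 0.8 * x1
    d$yc <- mu(d$x1) + 0.4 * d$t + rnorm(n, 0, 0.5)
    fit <- d[1:300, ]; cal <- d[301:500, ]; test <- d[501:600, ]
    cfg <- conformal_config(alpha = 0.1, weight_mode = "uniform",
                            outcome = "yc",
                            quantile_learner = list(nrounds = 60,
                                                    max_depth = 2, eta = 0.1,
                                                    min_child_weight = 10))
    qb1 <- fit_quantile_bounds(fit, 1L, cfg, covariates = c("x1", "x2"),
                               alpha = 0.1)
    iv <- weighted_conformal_counterfactual(qb1, cal, test, cfg)
    # fresh draws of the arm-1 potential outcome for the test rows
    y1 <- mu(test$x1) + 0.4 + rnorm(100, 0, 0.5)
    covered[r] <- mean(iv$lo <= y1 & y1 <= iv$hi)
  }
  expect_gte(mean(covered), 0.9 - 2 * sd(covered) / sqrt(30))
})

test_that("weighted conformal requires propensities and enough calibration", {
  set.seed(30)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), t = rbinom(100, 1, 0.5),
                  yc = rnorm(100))
  cfg <- conformal_config(outcome = "yc")
  qb <- fit_quantile_bounds(d, 1L, cfg, covariates = c("x1", "x2"))
  expect_error(weighted_conformal_counterfactual(qb, d[1:30, ], d, cfg),
               "25 calibration")
  expect_error(weighted_conformal_counterfactual(qb, d, d, cfg),
               "require e_calib")
})

test_that("nested ITE intervals are valid, seeded and ordered", {
  sim <- generate_cohort(default_cohort_spec(n = 2000, seed = 51))
  cfg <- conformal_config(outcome = "y_latent", seed = 51)
  iv <- nested_ite_intervals(sim$cohort, cfg)
  expect_s3_class(iv, "ite_intervals")
  expect_true(all(iv$lo <= iv$point & iv$point <= iv$hi))
  expect_gte(mean(iv$lo <= sim$truth$ite_latent &
                    sim$truth$ite_latent <= iv$hi), 0.95)
  # reruns reproduce exactly; splits partition the cohort
  iv2 <- nested_ite_intervals(sim$cohort, cfg)
  expect_identical(as.data.frame(iv), as.data.frame(iv2))
  sp <- attr(iv, "splits")
  expect_identical(sort(c(sp$train, sp$eval)), seq_len(2000L))
  # supplied point estimates are clamped into the interval
  pt <- sim$truth$ite_latent
  iv3 <- nested_ite_intervals(sim$cohort, cfg, point = pt)
  expect_true(all(iv3$lo <= iv3$point & iv3$point <= iv3$hi))
})

test_that("interval width shrinks as alpha grows and as noise vanishes", {
  sim <- generate_cohort(default_cohort_spec(n = 2000, seed = 52))
  widths <- vapply(c(0.01, 0.1, 0.2), function(a) {
    cfg <- conformal_config(alpha = a, outcome = "y_latent", seed = 52)
    iv <- nested_ite_intervals(sim$cohort, cfg)
    mean(iv$hi - iv$lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  sim_quiet <- generate_cohort(default_cohort_spec(n = 2000, seed = 52,
                                                   latent_sd = 0.02))
  cfg <- conformal_config(outcome = "y_latent", seed = 52)
  ivq <- nested_ite_intervals(sim_quiet$cohort, cfg)
  expect_gte(mean(ivq$lo <= sim_quiet$truth$ite_latent &
                    sim_quiet$truth$ite_latent <= ivq$hi), 0.99)
  iv_noisy <- nested_ite_intervals(sim$cohort, cfg)
  expect_lt(mean(ivq$hi - ivq$lo), mean(iv_noisy$hi - iv_noisy$lo))
})

test_that("a perfectly learnable noiseless outcome gives tight full-coverage intervals", {
  set.seed(60)
  n <- 3000
  d <- data.frame(x1 = runif(n, -1, 1), x2 = rnorm(n))
  d$t <- rbinom(n, 1, 0.5)
  tau <- -0.3
  d$yc <- 0.8 * d$x1 + tau * d$t   # zero noise, one smooth driver
  cfg <- conformal_config(outcome = "yc", weight_mode = "uniform",
                          seed = 60)
  iv <- nested_ite_intervals(d, cfg, covariates = c("x1", "x2"))
  expect_equal(mean(iv$lo <= tau & tau <= iv$hi), 1)
  expect_lt(mean(abs(iv$point - tau)), 0.15)
  # same design with outcome noise: intervals must be much wider
  d_noisy <- d
  d_noisy$yc <- d_noisy$yc + rnorm(n, 0, 0.5)
  ivn <- nested_ite_intervals(d_noisy, cfg, covariates = c("x1", "x2"))
  expect_lt(mean(iv$hi - iv$lo), 0.35 * mean(ivn$hi - ivn$lo))
})

test_that("binary-outcome intervals stay inside the probability-difference range", {
  sim <- generate_cohort(default_cohort_spec(n = 2000, seed = 53))
  iv <- nested_ite_intervals(sim$cohort, conformal_config(seed = 53))
  expect_true(all(iv$lo >= -1 & iv$hi <= 1))
})

test_that("the stratified summary respects its contract", {
  sim <- generate_cohort(default_cohort_spec(n = 4000, seed = 54))
  cfg <- conformal_config(outcome = "y_latent", seed = 54)
  iv <- nested_ite_intervals(sim$cohort, cfg, point = sim$truth$ite_latent)
  smry <- stratified_ite_summary(iv, sim$cohort)
  expect_true(all(smry$iqr_low <= smry$iqr_high))
  expect_equal(sum(smry$n), sum(sim$cohort$t == 0))
  # diabetes strata carry the strongest benefit, by generator construction
  dm_strata <- grepl("dm", smry$stratum)
  expect_true(all(smry$mean_ite[dm_strata] <
                    smry$mean_ite[smry$stratum %in% c("none", "dlp")]))
  expect_match(smry$stratum[which.min(smry$mean_ite)], "dm")
  expect_error(stratified_ite_summary(iv, sim$cohort,
                                      strata = c("af", "dm")),
               "must not define")
  # constant points: every stratum mean equal, zero IQR width
  iv_const <- iv
  iv_const$point <- -0.02
  sc <- stratified_ite_summary(iv_const, sim$cohort)
  expect_true(all(abs(sc$mean_ite + 0.02) < 1e-12))
  expect_true(all(sc$iqr_high - sc$iqr_low < 1e-12))
})
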