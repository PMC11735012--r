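test_that("identical specs reproduce identical cohorts and ground truth", {
  spec <- default_cohort_spec(n = 500, seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
})

test_that("cohorts satisfy their structural invariants", {
  sim <- cached_sim(5000, 12)
  d <- sim$cohort
  for (v in c("sex", "ckd", "af", "ht", "dm", "dlp", "t", "y"))
    expect_true(all(d[[v]] %in% c(0, 1)), info = v)
  expect_true(all(d$age > 18))
  expect_false(anyNA(d))
  expect_equal(sim$truth$ite, sim$truth$p1 - sim$truth$p0, tolerance = 1e-12)
  expect_true(all(abs(sim$truth$ite) <= 1))
  expect_equal(sim$truth$ite_latent, sim$truth$mu1 - sim$truth$mu0,
               tolerance = 1e-12)
})

test_that("the null structural model gives 50% incidence and zero effects", {
  sim <- generate_cohort(null_cohort_spec(n = 20000, seed = 4))
  expect_equal(mean(sim$cohort$y), 0.5, tolerance = 0.02)
  expect_true(all(sim$truth$ite == 0))
  gt <- ground_truth_effects(null_cohort_spec(n = 10, seed = 4), "af",
                             n_mc = 5000)
  expect_equal(gt$risk_difference, 0, tolerance = 1e-12)
  expect_equal(gt$risk_ratio, 1, tolerance = 1e-12)
})

test_that("spec validation rejects bad inputs", {
  expect_error(default_cohort_spec(n = 0), "positive")
  good <- default_cohort_spec(n = 10)
  co <- good$coefficients
  co$y <- c(co$y, sex = 1)  # no sex -> y edge in the diagram
  expect_error(cohort_spec(10, 1, co, good$intercepts), "absent edge")
  co2 <- good$coefficients
  names(co2)[1] <- "nonsense"
  expect_error(cohort_spec(10, 1, co2, good$intercepts), "unknown node")
})

test_that("default calibration hits the marginal and stratified rates", {
  d <- cached_sim(50000, 12)$cohort
  # binomial sampling bands (plus a small calibration margin) around the
  # target rates
  expect_lt(abs(mean(d$y) - 0.035), 3 * sqrt(0.035 * 0.965 / 5e4) + 0.001)
  expect_lt(abs(mean(d$y[d$af == 1]) - 0.13), 0.012)
  expect_lt(abs(mean(d$y[d$af == 0]) - 0.02), 0.004)
  expect_lt(abs(mean(d$y[d$ht == 1]) - 0.04), 0.005)
  expect_lt(abs(mean(d$y[d$ht == 0]) - 0.01), 0.004)
  expect_lt(abs(mean(d$y[d$dm == 1]) - 0.04), 0.005)
  expect_lt(abs(mean(d$y[d$dm == 0]) - 0.03), 0.005)
})

test_that("analytic ground truth matches the forced-treatment Monte Carlo", {
  sim <- cached_sim(50000, 12)
  gt <- ground_truth_effects(sim$spec, "t", n_mc = 100000, seed = 5)
  expect_lt(abs(mean(sim$truth$ite) - gt$risk_difference),
            3 * gt$se_rd + 0.002)
})

test_that("forced-exposure effects match an independent two-world simulator", {
  spec <- default_cohort_spec(n = 10, seed = 2)
  gt <- ground_truth_effects(spec, "af", n_mc = 200000, seed = 31)
  osim <- oracle_two_world(spec, "af", n = 200000, seed = 632)
  expect_lt(abs(gt$risk_difference - osim$rd), 4 * osim$se)
  expect_gt(gt$risk_ratio, 1)
})

test_that("a single direct edge reproduces the closed-form risk difference", {
  # only age -> y and af -> y active: the true effect integrates the
  # logistic contrast over the truncated-normal age distribution
  spec <- null_cohort_spec(n = 10, seed = 1, p = 0.3)
  spec$coefficients$y[["age"]] <- 0.5
  spec$coefficients$y[["af"]] <- 1.5
  ex <- spec$exogenous
  p_lo <- pnorm(ex$age_min, ex$age_mean, ex$age_sd)
  dens <- function(a) dnorm(a, ex$age_mean, ex$age_sd) / (1 - p_lo)
  contrast <- function(a) {
    s <- (a - ex$age_mean) / ex$age_sd
    (plogis(spec$intercepts[["y"]] + 0.5 * s + 1.5) -
       plogis(spec$intercepts[["y"]] + 0.5 * s)) * dens(a)
  }
  truth <- integrate(contrast, ex$age_min, Inf)$value
  gt <- ground_truth_effects(spec, "af", n_mc = 300000, seed = 8)
  expect_lt(abs(gt$risk_difference - truth), 4 * gt$se_rd + 1e-4)
})

test_that("zeroing the af->y edge removes the atrial fibrillation effect", {
  spec <- default_cohort_spec(n = 10, seed = 3)
  spec$coefficients$y[["af"]] <- 0
  gt <- ground_truth_effects(spec, "af", n_mc = 100000, seed = 9)
  expect_lt(abs(gt$risk_difference), 3 * gt$se_rd + 1e-6)
  expect_equal(gt$risk_ratio, 1, tolerance = 0.02)
})

test_that("treatment is protective within the diabetic stratum", {
  gt <- ground_truth_effects(default_cohort_spec(n = 10, seed = 3), "t",
                             n_mc = 100000, seed = 10,
                             condition = list(dm = 1))
  expect_lt(gt$risk_difference, 0)
  expect_error(ground_truth_effects(default_cohort_spec(n = 10), "t",
                                    condition = list(y = 1)),
               "descendant")
  expect_error(ground_truth_effects(default_cohort_spec(n = 10), "bmi"),
               "unknown exposure")
})

test_that("cohort CSV export round-trips losslessly", {
  sim <- cached_sim(5000, 12)
  small <- sim$cohort[1:10, ]
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  export_cohort(small, path)
  back <- read_cohort(path)
  expect_identical(names(back),
                   c("age", "sex", "bmi", "ckd", "af", "ht", "dm", "dlp",
                     "t", "y", "y_latent"))
  for (v in names(back))
    expect_identical(back[[v]], small[[v]], info = v)
  # empty cohort -> header-only file
  export_cohort(small[0, ], path)
  expect_length(readLines(path), 1L)
  # large cohort preserves row count
  export_cohort(sim$cohort, path)
  expect_equal(nrow(read_cohort(path)), 5000L)
  # ground-truth table schema
  export_ground_truth(sim$truth[1:5, ], path)
  expect_identical(readLines(path)[1], "p1,p0,ite,mu1,mu0,ite_latent")
})
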