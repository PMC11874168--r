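test_that("covariate generator matches the configured proportions", {
  set.seed(101)
  n <- 10000
  cov <- simulate_covariates(n)
  # binomial Monte-Carlo bounds: 3 * sqrt(p (1 - p) / n)
  bound <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cov$desk == "stand-biased") - 150 / 256),
            bound(150 / 256))
  expect_lt(abs(mean(cov$sex == "boy") - 133 / 256), bound(133 / 256))
  expect_lt(abs(mean(cov$race == "white") - 176 / 256), bound(176 / 256))
  expect_lt(abs(mean(cov$age) - 7.86), 3 * 0.80 / sqrt(n))
  expect_equal(sort(unique(cov$school_id)),
               c("school_1", "school_2", "school_3"))
  # round-robin assignment balances cluster sizes to within one
  expect_lte(diff(range(table(cov$school_id))), 1)
})

test_that("n = n_schools gives exactly one subject per school", {
  set.seed(5)
  cov <- simulate_covariates(3, n_schools = 3)
  expect_equal(unname(table(cov$school_id)), rep(1L, 3), ignore_attr = TRUE)
})

test_that("invalid proportions are rejected naming the field", {
  expect_error(simulate_covariates(10, list(boy = 1.5, white = 0.5,
                                            stand = 0.5)), "'boy'")
  expect_error(simulate_covariates(10, list(boy = 0.5, white = 0.5)),
               "stand")
})

test_that("curve generator hits the configured moments", {
  set.seed(77)
  g <- time_grid(30)
  cv <- simulate_curves(5000, g)
  subj_means <- summarize_scalar_sdee(cv, g)
  expect_lt(abs(mean(subj_means) - 1.32), 3 * 0.32 / sqrt(5000))
  expect_lt(abs(sd(subj_means) - 0.32), 0.02)
  expect_gte(min(cv), 0.05) # floor
})

test_that("degenerate curve generator returns the template exactly", {
  set.seed(1)
  cm <- list(sd_sdee = 0, noise_sd = 0)
  cv <- simulate_curves(5, time_grid(30), cm)
  expect_equal(cv[1, ], cv[5, ])
  expect_equal(sum(cv[1, ]) / 30, 1.32, tolerance = 1e-12)
})

test_that("curve generator is deterministic under a fixed seed", {
  set.seed(99); a <- simulate_curves(20, time_grid(30))
  set.seed(99); b <- simulate_curves(20, time_grid(30))
  expect_identical(a, b)
})

test_that("outcome model components behave as specified", {
  g <- time_grid(30)
  zero_truth <- simulation_truth(
    n = 50, beta0 = 1.7, beta_cov = c(age = 0, sex = 0, race = 0, desk = 0),
    beta_fun = function(t) rep(0, length(t)),
    sigma2_school = 0, sigma2_resid = 0)
  set.seed(2)
  cov <- simulate_covariates(50)
  cv <- simulate_curves(50, g)
  # zero model: Y is exactly the intercept
  expect_equal(simulate_outcome(cov, cv, g, zero_truth), rep(1.7, 50))
  # constant functional coefficient: the integral term is c times the
  # per-subject quadrature mean of the curve
  const_truth <- simulation_truth(
    n = 50, beta0 = 0, beta_cov = c(age = 0, sex = 0, race = 0, desk = 0),
    beta_fun = function(t) rep(0.8, length(t)),
    sigma2_school = 0, sigma2_resid = 0)
  expect_equal(simulate_outcome(cov, cv, g, const_truth),
               0.8 * summarize_scalar_sdee(cv, g), tolerance = 1e-12)
  expect_error(simulate_outcome(cov, cv[1:10, ], g, zero_truth), "subjects")
})

test_that("school and residual noise reproduce the target ICC", {
  # pure noise model so the ANOVA estimator sees only b_j + eps;
  # 100 clusters of 50 keep the estimator sd below ~0.015
  truth <- simulation_truth(
    n = 5000, n_schools = 100, beta0 = 0,
    beta_cov = c(age = 0, sex = 0, race = 0, desk = 0),
    beta_fun = function(t) rep(0, length(t)),
    sigma2_school = 0.10 * 0.02, sigma2_resid = 0.90 * 0.02)
  set.seed(31)
  g <- time_grid(30)
  cov <- simulate_covariates(5000, n_schools = 100)
  y <- simulate_outcome(cov, simulate_curves(5000, g), g, truth)
  expect_lt(abs(anova_icc(y, cov$school_id) - 0.10), 0.02)
})

test_that("simulate_study composes to the default study shape", {
  study <- simulate_study(simulation_truth(), seed = 6)
  expect_s3_class(study, "sdee_study")
  expect_equal(study$n, 256)
  expect_equal(length(unique(study$covariates$school_id)), 3)
  expect_equal(study$grid$m, 30)
  expect_equal(study$covariates$bmi, exp(study$covariates$log_bmi))
  expect_identical(study$seed, 6L)
  # determinism: same truth + seed => identical study
  expect_identical(simulate_study(simulation_truth(), seed = 6), study)
})

test_that("replicated default studies center on the published moments", {
  # 200 replicates; the bound combines the within-study sd of a BMI mean
  # (2.98/sqrt(256)) with the school-level multiplicative noise, giving a
  # replicate-mean sd of ~0.4, so 3 * 0.4 / sqrt(200) ~ 0.09
  truth <- simulation_truth()
  bmi_means <- vapply(1:200, function(s) {
    mean(simulate_study(truth, seed = s)$covariates$bmi)
  }, numeric(1))
  expect_lt(abs(mean(bmi_means) - 17.40), 0.09)
  sdee_means <- vapply(1:50, function(s) {
    st <- simulate_study(truth, seed = s)
    mean(summarize_scalar_sdee(st$curves, st$grid))
  }, numeric(1))
  expect_lt(abs(mean(sdee_means) - 1.32), 0.01)
})

test_that("moment calibration holds at n = 10,000", {
  truth <- simulation_truth(n = 10000, n_schools = 100)
  study <- simulate_study(truth, seed = 13)
  expect_true(abs(mean(summarize_scalar_sdee(study$curves, study$grid)) -
                    1.32) < 0.02)
  expect_gt(mean(study$covariates$bmi), 17.2)
  expect_lt(mean(study$covariates$bmi), 17.6)
  expect_lt(abs(sd(study$covariates$bmi) - 2.98), 0.25)
})

test_that("truth construction rejects impossible configurations", {
  expect_error(simulation_truth(n = 2, n_schools = 3), "n_schools")
  expect_error(simulation_truth(icc = 1.2), "icc")
  expect_error(simulation_truth(curve_model = list(noise_sd = 5)),
               "noise_sd too large")
  expect_error(
    simulation_truth(beta_cov = c(age = 0, sex = 0, race = 0, desk = 5)),
    "exceeds the target marginal variance")
  expect_error(simulation_truth(sigma2_school = 0.1), "both")
})
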