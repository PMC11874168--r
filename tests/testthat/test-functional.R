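test_that("fit_fmem is exactly the engine fit on precomputed scores", {
  study <- small_study(n = 96, seed = 21)
  fm <- fit_fmem(study, G = 5)
  basis <- build_bspline_basis(5, 3, grid = study$grid)
  scores <- score_functional_covariate(study$curves, study$grid, basis)
  X <- cbind("(Intercept)" = 1, scores,
             funqee:::encode_covariates(study$covariates))
  engine <- fit_lmem(study$covariates$log_bmi, X,
                     study$covariates$school_id)
  expect_identical(fm$engine$coefficients$estimate,
                   engine$coefficients$estimate)
  expect_identical(fm$gamma_hat,
                   setNames(engine$coefficients$estimate[2:6],
                            paste0("c", 1:5)))
  # the curve is definitionally eval_matrix %*% gamma
  expect_equal(fm$beta_curve$values,
               drop(basis$eval_matrix %*% fm$gamma_hat), tolerance = 1e-12)
})

test_that("functional fits are deterministic given the data", {
  study <- small_study(n = 96, seed = 22)
  expect_identical(fit_fmem(study, G = 4), fit_fmem(study, G = 4))
  f1 <- fit_fqmem(study, tau = 0.5, G = 4)
  f2 <- fit_fqmem(study, tau = 0.5, G = 4)
  expect_identical(f1$gamma_hat, f2$gamma_hat)
})

test_that("constant true coefficient is recovered by the FMEM", {
  truth <- simulation_truth(n = 2000, n_schools = 20,
                            beta_fun = function(t) rep(0.366, length(t)))
  study <- simulate_study(truth, seed = 23)
  fm <- fit_fmem(study, G = 5)
  int_est <- sum(study$grid$weights * fm$beta_curve$values)
  expect_lt(abs(int_est - 0.366), 0.05)
})

test_that("AIC selection honors range, ties and failure bookkeeping", {
  study <- small_study(n = 96, seed = 24)
  sel <- select_G_by_aic(study, "fmem", G_range = 4:7)
  expect_equal(sel$aic_table$G, 4:7)
  expect_equal(sel$G, sel$aic_table$G[which.min(sel$aic_table$aic)])
  # duplicates collapse to a single fit of the smaller G
  dup <- select_G_by_aic(study, "fmem", G_range = c(4, 4))
  expect_equal(dup$G, 4)
  expect_equal(nrow(dup$aic_table), 1)
  expect_error(select_G_by_aic(study, "fqmem", G_range = 4:5), "tau")
  expect_error(select_G_by_aic(study, "fmem", G_range = integer(0)),
               "empty")
})

test_that("median FQMEM agrees with the FMEM under symmetric errors", {
  # n = 8000 so that estimation noise in the two coefficient curves is
  # small relative to the smooth signal; at moderate n the median- and
  # mean-regression curves decorrelate through sampling noise alone
  truth <- simulation_truth(n = 8000, n_schools = 40)
  study <- simulate_study(truth, seed = 201)
  fm <- fit_fmem(study, G = 4)
  fq <- fit_fqmem(study, tau = 0.5, G = 4)
  expect_gt(cor(fm$beta_curve$values, fq$beta_curve$values), 0.9)
})

test_that("with identical curves the FQMEM absorbs the sample median", {
  truth <- simulation_truth(n = 200, n_schools = 4,
                            beta_cov = c(age = 0, sex = 0, race = 0,
                                         desk = 0),
                            sigma2_school = 0, sigma2_resid = 0.02)
  study <- simulate_study(truth, seed = 26)
  study$curves[] <- matrix(rep(study$curves[1, ], each = study$n),
                           nrow = study$n)
  fq <- fit_fqmem(study, tau = 0.5, G = 4, covariates = character(0))
  sc <- score_functional_covariate(study$curves[1, ], study$grid, fq$basis)
  fitted <- fq$coefficients$estimate[1] + sum(fq$gamma_hat * sc)
  y <- sort(study$covariates$log_bmi)
  gap <- max(diff(y[(study$n / 2 - 1):(study$n / 2 + 2)]))
  expect_lt(abs(fitted - median(study$covariates$log_bmi)), gap + 1e-3)
})

test_that("bootstrap bands are seed-reproducible and level-monotone", {
  study <- small_study(n = 96, seed = 27)
  fitter <- function(s) fit_fmem(s, G = 4)
  b1 <- bootstrap_functional_inference(study, fitter, B = 60, seed = 71)
  b2 <- bootstrap_functional_inference(study, fitter, B = 60, seed = 71)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$covariate_table, b2$covariate_table)
  b90 <- bootstrap_functional_inference(study, fitter, B = 60, seed = 71,
                                        level = 0.90)
  expect_true(all(b90$lower >= b1$lower - 1e-12))
  expect_true(all(b90$upper <= b1$upper + 1e-12))
  # replicate curves live inside the band hull by construction
  expect_true(all(b1$lower <= apply(b1$beta_replicates, 1, max)))
})

test_that("permutation scheme reproduces the original fit exactly", {
  study <- small_study(n = 96, seed = 28)
  b <- bootstrap_functional_inference(study, function(s) fit_fmem(s, G = 4),
                                      B = 50, seed = 5,
                                      scheme = "permutation")
  # refits on reordered rows agree up to profile-optimizer resolution
  expect_lt(max(abs(b$lower - b$estimate)), 1e-4)
  expect_lt(max(abs(b$upper - b$estimate)), 1e-4)
  expect_lt(max(b$upper - b$lower), 1e-4)
})

test_that("failed replicates are counted and trigger the 10% warning", {
  study <- small_study(n = 96, seed = 29)
  k <- 0
  flaky <- function(s) {
    k <<- k + 1
    if (k > 1 && k %% 3 == 0) stop("synthetic failure")
    fit_fmem(s, G = 4)
  }
  expect_warning(
    b <- bootstrap_functional_inference(study, flaky, B = 60, seed = 6),
    "> 10%")
  expect_lt(b$B_used, 60)
  expect_match(b$warnings, "replicates failed")
  j <- 0
  always_fail_after_first <- function(s) {
    j <<- j + 1
    if (j > 1) stop("synthetic failure")
    fit_fmem(s, G = 4)
  }
  expect_error(bootstrap_functional_inference(
    study, always_fail_after_first, B = 50, seed = 1), "every bootstrap")
  expect_error(bootstrap_functional_inference(
    study, function(s) fit_fmem(s, G = 4), B = 10), "B >= 50")
})

test_that("significant windows enumerate exceedance runs", {
  m <- 30
  lo <- rep(-1, m); hi <- rep(1, m)
  # run at grid points 3..9 corresponds to t in [0.1, 0.3]
  lo2 <- lo; lo2[3:9] <- 0.2
  w <- significant_windows(fake_band(lo2, hi))
  expect_equal(nrow(w), 1)
  expect_equal(w$t_start, 0.1)
  expect_equal(w$t_end, 0.3)
  expect_equal(w$direction, "positive")
  # straddling zero everywhere: no windows
  expect_equal(nrow(significant_windows(fake_band(lo, hi))), 0)
  # two separated runs with mixed directions
  lo3 <- lo; hi3 <- hi
  lo3[5:8] <- 0.1
  hi3[20:22] <- -0.1
  w3 <- significant_windows(fake_band(lo3, hi3))
  expect_equal(w3$start_index, c(5L, 20L))
  expect_equal(w3$end_index, c(8L, 22L))
  expect_equal(w3$direction, c("positive", "negative"))
})

test_that("estimation error of the coefficient curve shrinks with n", {
  # integrated squared error against the smooth truth at growing n
  truth_for <- function(n, J) simulation_truth(n = n, n_schools = J)
  ise <- vapply(list(c(250, 5), c(1000, 10), c(4000, 20)), function(sz) {
    study <- simulate_study(truth_for(sz[1], sz[2]), seed = 30)
    fm <- fit_fmem(study, G = 7)
    b1 <- 0.366 + 0.2 * sin(2 * pi * study$grid$points)
    sum(study$grid$weights * (fm$beta_curve$values - b1)^2)
  }, numeric(1))
  expect_true(all(diff(ise) < 0))
})
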