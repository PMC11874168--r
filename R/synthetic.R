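#' Ground-truth configuration for the synthetic study generator
#'
#' Bundles every parameter of the data-generating model: the outcome model
#' \deqn{Y_{ij} = \beta_0 + \int_0^1 \beta_1(t) Z_{ij}(t)\,dt +
#'   \sum_k \beta_{2k} X_{ijk} + b_j + \varepsilon_{ij},}
#' with \eqn{b_j \sim N(0, \sigma_j^2)} a school random intercept and
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)}, plus the covariate
#' distributions and the SDEE curve generator. Defaults emulate a
#' three-school stand-biased-desk trial: n = 256 students, 30 hourly SDEE
#' means averaging 1.32 (sd 0.32) cal/min, mean BMI 17.40 (sd 2.98) kg/m^2,
#' and a school intraclass correlation of 0.10.
#'
#' The school and residual variances are derived at construction time by
#' closed-form moment accounting: the marginal variance of log(BMI) implied
#' by `bmi_mean`/`bmi_sd` (lognormal moments), minus the variance
#' contributed by the covariates and the functional term, is split between
#' school and residual according to `icc`. Supplying `sigma2_school` /
#' `sigma2_resid` directly overrides this.
#'
#' @param n Number of subjects (default 256).
#' @param n_schools Number of school clusters (default 3).
#' @param m Hourly observations per curve (default 30).
#' @param beta0 Intercept; `NULL` (default) solves it so that the marginal
#'   mean BMI matches `bmi_mean`.
#' @param beta_cov Named coefficients for `age`, `sex` (boy = 1), `race`
#'   (white = 1) and `desk` (stand-biased = 1), on the log(BMI) scale.
#' @param beta_fun True functional coefficient: a function of `t` on
#'   `[0, 1]`, or a numeric vector on the grid. Default
#'   `0.366 + 0.2 sin(2 pi t)`, a smooth curve integrating to the scalar
#'   SDEE slope 0.366.
#' @param icc Target intraclass correlation \eqn{\sigma_j^2 / (\sigma_j^2 +
#'   \sigma^2)} (default 0.10).
#' @param sigma2_school,sigma2_resid Optional explicit variance components;
#'   both must be given together to bypass the moment calibration.
#' @param proportions Named list of Bernoulli probabilities `boy`, `white`,
#'   `stand` (defaults 133/256, 176/256, 150/256).
#' @param age_mean_sd Length-2 numeric, mean and sd of age in years
#'   (default `c(7.86, 0.80)`).
#' @param curve_model Named list for the SDEE curve generator:
#'   `mean_sdee`, `sd_sdee` (population mean/sd of the per-subject overall
#'   mean, cal/min), `noise_sd` (hourly Gaussian noise, cal/min), `floor`
#'   (lower clip, cal/min), `template` (smooth diurnal shape function,
#'   rescaled internally so the population mean matches `mean_sdee`).
#' @param bmi_mean,bmi_sd Target marginal moments of BMI (kg/m^2).
#' @param seed Default seed recorded in the truth and used by
#'   [simulate_study()].
#' @return An object of class `sdee_truth`.
#' @seealso [simulate_study()]
#' @export
simulation_truth <- function(n = 256L,
                             n_schools = 3L,
                             m = 30L,
                             beta0 = NULL,
                             beta_cov = c(age = -0.002, sex = -0.045,
                                          race = -0.017, desk = -0.049),
                             beta_fun = function(t) 0.366 + 0.2 * sin(2 * pi * t),
                             icc = 0.10,
                             sigma2_school = NULL,
                             sigma2_resid = NULL,
                             proportions = list(boy = 133 / 256,
                                                white = 176 / 256,
                                                stand = 150 / 256),
                             age_mean_sd = c(7.86, 0.80),
                             curve_model = list(),
                             bmi_mean = 17.40,
                             bmi_sd = 2.98,
                             seed = 1L) {
  n <- as.integer(n); n_schools <- as.integer(n_schools)
  if (n < n_schools || n_schools < 1L) {
    stop("need n >= n_schools >= 1")
  }
  validate_proportions(proportions)
  if (length(age_mean_sd) != 2L || age_mean_sd[2] < 0) {
    stop("age_mean_sd must be c(mean, sd) with sd >= 0")
  }
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)")

  cm <- utils::modifyList(default_curve_model(), curve_model)
  if (cm$mean_sdee <= 0 || cm$sd_sdee < 0 || cm$noise_sd < 0 || cm$floor < 0) {
    stop("curve_model moments must be nonnegative (mean_sdee > 0)")
  }
  grid <- time_grid(m)
  beta1 <- eval_beta_fun(beta_fun, grid$points)
  req <- c("age", "sex", "race", "desk")
  if (!all(req %in% names(beta_cov))) {
    stop("beta_cov must name coefficients for: ",
         paste(setdiff(req, names(beta_cov)), collapse = ", "))
  }
  beta_cov <- beta_cov[req]

  # lognormal moment matching: target mean/var of Y = log(BMI)
  cv2 <- (bmi_sd / bmi_mean)^2
  var_y <- log(1 + cv2)
  mean_y <- log(bmi_mean) - var_y / 2

  mom <- curve_moments(cm, grid)
  # functional term A_i * int beta1 mu + sum_k beta1(t_k) w_k noise_k
  int_b1_mu <- sum(grid$weights * beta1 * mom$mu)
  var_fun <- int_b1_mu^2 * mom$var_amp +
    sum((beta1 * grid$weights)^2) * cm$noise_sd^2
  p <- proportions
  var_cov <- beta_cov[["age"]]^2 * age_mean_sd[2]^2 +
    beta_cov[["sex"]]^2 * p$boy * (1 - p$boy) +
    beta_cov[["race"]]^2 * p$white * (1 - p$white) +
    beta_cov[["desk"]]^2 * p$stand * (1 - p$stand)

  if (is.null(sigma2_school) != is.null(sigma2_resid)) {
    stop("supply both sigma2_school and sigma2_resid, or neither")
  }
  if (is.null(sigma2_school)) {
    v <- var_y - var_fun - var_cov
    if (v <= 0) {
      stop("systematic variance exceeds the target marginal variance of ",
           "log(BMI); reduce effect sizes or raise bmi_sd")
    }
    sigma2_school <- icc * v
    sigma2_resid <- (1 - icc) * v
  }
  if (sigma2_school < 0 || sigma2_resid < 0) stop("variances must be >= 0")

  if (is.null(beta0)) {
    e_cov <- beta_cov[["age"]] * age_mean_sd[1] +
      beta_cov[["sex"]] * p$boy +
      beta_cov[["race"]] * p$white +
      beta_cov[["desk"]] * p$stand
    beta0 <- mean_y - int_b1_mu - e_cov
  }

  structure(
    list(n = n, n_schools = n_schools, m = m,
         beta0 = beta0, beta_cov = beta_cov, beta_fun = beta_fun,
         sigma2_school = sigma2_school, sigma2_resid = sigma2_resid,
         icc = sigma2_school / max(sigma2_school + sigma2_resid, .Machine$double.eps),
         proportions = proportions, age_mean_sd = age_mean_sd,
         curve_model = cm, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         seed = as.integer(seed)),
    class = "sdee_truth"
  )
}

default_curve_model <- function() {
  list(
    mean_sdee = 1.32,
    sd_sdee = 0.32,
    noise_sd = 0.25,
    floor = 0.05,
    # bimodal diurnal shape: morning recess and afternoon activity bumps
    template = function(t) {
      0.55 + 1.4 * exp(-(t - 0.25)^2 / (2 * 0.12^2)) +
        1.1 * exp(-(t - 0.70)^2 / (2 * 0.15^2))
    }
  )
}

# population template on the grid plus the lognormal amplitude variance
# implied by the target per-subject-mean moments
curve_moments <- function(cm, grid) {
  shp <- if (is.function(cm$template)) {
    cm$template(grid$points)
  } else if (is.numeric(cm$template) && length(cm$template) == grid$m) {
    cm$template # shape values already on the grid (e.g. from a config file)
  } else {
    stop("curve template must be a function of t or a length-m numeric vector")
  }
  if (any(shp <= 0)) stop("curve template must be positive on the grid")
  mu <- cm$mean_sdee * shp / sum(grid$weights * shp)
  var_amp <- (cm$sd_sdee^2 - cm$noise_sd^2 / grid$m) / cm$mean_sdee^2
  if (var_amp < 0) {
    stop("noise_sd too large: hourly noise alone exceeds the target sd ",
         "of the per-subject mean SDEE")
  }
  list(mu = mu, var_amp = var_amp)
}

eval_beta_fun <- function(beta_fun, points) {
  if (is.function(beta_fun)) {
    v <- beta_fun(points)
  } else {
    v <- as.numeric(beta_fun)
  }
  if (length(v) != length(points) || any(!is.finite(v))) {
    stop("beta_fun must evaluate to one finite value per grid point")
  }
  v
}

validate_proportions <- function(proportions) {
  req <- c("boy", "white", "stand")
  if (!is.list(proportions) || !all(req %in% names(proportions))) {
    stop("proportions must be a named list with fields: ",
         paste(req, collapse = ", "))
  }
  for (f in req) {
    p <- proportions[[f]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("invalid proportion for field '", f, "': must be in [0, 1]")
    }
  }
  invisible(proportions)
}

#' Simulate subject-level covariates
#'
#' Draws scalar covariates for `n` students: balanced school assignment
#' (round-robin over a shuffled subject order, so cluster sizes differ by at
#' most one), Bernoulli sex/race/desk indicators, and Gaussian age.
#' Uses the current R random-number stream; seed with [set.seed()] or via
#' [simulate_study()].
#'
#' @param n Number of subjects.
#' @param proportions Named list with probabilities `boy`, `white`, `stand`.
#' @param age_mean_sd Length-2 numeric `c(mean, sd)` for age.
#' @param n_schools Number of schools.
#' @return A data.frame with columns `subject_id`, `school_id`, `age`,
#'   `sex` (`"boy"`/`"girl"`), `race` (`"white"`/`"non-white"`),
#'   `desk` (`"stand-biased"`/`"traditional"`).
#' @export
simulate_covariates <- function(n,
                                proportions = list(boy = 133 / 256,
                                                   white = 176 / 256,
                                                   stand = 150 / 256),
                                age_mean_sd = c(7.86, 0.80),
                                n_schools = 3L) {
  n <- as.integer(n); n_schools <- as.integer(n_schools)
  if (n < n_schools || n_schools < 1L) stop("need n >= n_schools >= 1")
  validate_proportions(proportions)
  school <- integer(n)
  school[sample.int(n)] <- rep_len(seq_len(n_schools), n)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    school_id = sprintf("school_%d", school),
    age = stats::rnorm(n, age_mean_sd[1], age_mean_sd[2]),
    sex = ifelse(stats::runif(n) < proportions$boy, "boy", "girl"),
    race = ifelse(stats::runif(n) < proportions$white, "white", "non-white"),
    desk = ifelse(stats::runif(n) < proportions$stand,
                  "stand-biased", "traditional"),
    stringsAsFactors = FALSE
  )
}

#' Simulate SDEE curves on a common grid
#'
#' Each curve is `A_i * mu(t) + e_ik`, a smooth bimodal diurnal template
#' `mu` scaled by a subject-level lognormal amplitude (mean 1) plus hourly
#' Gaussian noise, floored at `curve_model$floor` cal/min. The template is
#' rescaled so the population mean of the per-subject overall mean SDEE is
#' `curve_model$mean_sdee`, and the amplitude variance is solved so its
#' population sd is `curve_model$sd_sdee`.
#'
#' @param n Number of curves.
#' @param grid An [time_grid()] object.
#' @param curve_model Named list as in [simulation_truth()]; partial lists
#'   are completed with the defaults.
#' @return An `n x m` numeric matrix of nonnegative cal/min values.
#' @export
simulate_curves <- function(n, grid = time_grid(), curve_model = list()) {
  validate_grid(grid)
  cm <- utils::modifyList(default_curve_model(), curve_model)
  mom <- curve_moments(cm, grid)
  if (mom$var_amp > 0) {
    sdlog2 <- log(1 + mom$var_amp) # amplitude mean fixed at 1
    amp <- stats::rlnorm(n, meanlog = -sdlog2 / 2, sdlog = sqrt(sdlog2))
  } else {
    amp <- rep(1, n)
  }
  curves <- tcrossprod(amp, mom$mu)
  if (cm$noise_sd > 0) {
    curves <- curves + matrix(stats::rnorm(n * grid$m, 0, cm$noise_sd),
                              nrow = n)
  }
  pmax(curves, cm$floor)
}

#' Simulate log(BMI) outcomes from the functional mixed model
#'
#' Computes \eqn{Y_{ij} = \beta_0 + \int \beta_1(t) Z_{ij}(t) dt +
#' \sum_k \beta_{2k} X_{ijk} + b_j + \varepsilon_{ij}} with the integral
#' evaluated by the grid's quadrature rule, \eqn{b_j \sim N(0,\sigma_j^2)}
#' per school and \eqn{\varepsilon_{ij} \sim N(0,\sigma^2)}.
#'
#' @param covariates Covariate data.frame from [simulate_covariates()].
#' @param curves `n x m` SDEE matrix aligned with `covariates` rows.
#' @param grid The common [time_grid()].
#' @param truth An [simulation_truth()] object.
#' @return Numeric vector of log(BMI) values.
#' @export
simulate_outcome <- function(covariates, curves, grid, truth) {
  stopifnot(inherits(truth, "sdee_truth"))
  validate_grid(grid)
  if (nrow(covariates) != nrow(curves)) {
    stop("covariates and curves disagree on the number of subjects")
  }
  if (ncol(curves) != grid$m) {
    stop("curves have ", ncol(curves), " columns but the grid has ", grid$m)
  }
  beta1 <- eval_beta_fun(truth$beta_fun, grid$points)
  fun_term <- as.numeric(curves %*% (grid$weights * beta1))
  X <- encode_covariates(covariates)
  cov_term <- as.numeric(X %*% truth$beta_cov[colnames(X)])
  school <- factor(covariates$school_id)
  b <- stats::rnorm(nlevels(school), 0, sqrt(truth$sigma2_school))
  eps <- stats::rnorm(nrow(covariates), 0, sqrt(truth$sigma2_resid))
  truth$beta0 + fun_term + cov_term + b[as.integer(school)] + eps
}

# numeric design columns using the field's contrast directions:
# boy vs girl, white vs non-white, stand-biased vs traditional
encode_covariates <- function(covariates) {
  cbind(
    age = covariates$age,
    sex = as.numeric(covariates$sex == "boy"),
    race = as.numeric(covariates$race == "white"),
    desk = as.numeric(covariates$desk == "stand-biased")
  )
}

#' Simulate a complete study with known ground truth
#'
#' Composes [simulate_covariates()], [simulate_curves()] and
#' [simulate_outcome()] under a single seed and returns a study object that
#' every model-fitting function in the package accepts.
#'
#' @param truth An [simulation_truth()] configuration.
#' @param seed Integer seed; defaults to `truth$seed`. The same seed and
#'   truth always yield an identical study.
#' @return An object of class `sdee_study`: fields `grid`, `covariates`
#'   (including `bmi` and `log_bmi`), `curves`, `n`, `truth`, `seed`.
#' @examples
#' study <- simulate_study(simulation_truth(n = 64, seed = 7))
#' study$n
#' @export
simulate_study <- function(truth = simulation_truth(), seed = truth$seed) {
  stopifnot(inherits(truth, "sdee_truth"))
  set.seed(as.integer(seed))
  grid <- time_grid(truth$m)
  covariates <- simulate_covariates(truth$n, truth$proportions,
                                    truth$age_mean_sd, truth$n_schools)
  curves <- simulate_curves(truth$n, grid, truth$curve_model)
  log_bmi <- simulate_outcome(covariates, curves, grid, truth)
  covariates$bmi <- exp(log_bmi)
  covariates$log_bmi <- log_bmi
  new_study(grid, covariates, curves, truth = truth, seed = as.integer(seed))
}

# internal constructor shared by the simulator, the CSV reader and the
# bootstrap resampler
new_study <- function(grid, covariates, curves, truth = NULL, seed = NULL) {
  validate_grid(grid)
  stopifnot(nrow(covariates) == nrow(curves), ncol(curves) == grid$m)
  if (length(unique(covariates$school_id)) < 2L) {
    stop("a study needs >= 2 distinct schools")
  }
  if (any(covariates$bmi <= 0)) stop("bmi must be positive")
  if (max(abs(log(covariates$bmi) - covariates$log_bmi)) > 1e-8) {
    stop("log_bmi is not the natural log of bmi")
  }
  rownames(curves) <- covariates$subject_id
  structure(
    list(grid = grid, covariates = covariates, curves = curves,
         n = nrow(covariates), truth = truth, seed = seed),
    class = "sdee_study"
  )
}

#' @export
print.sdee_study <- function(x, ...) {
  cat(sprintf(
    "<sdee_study> %d subjects, %d schools, %d-point SDEE grid%s\n",
    x$n, length(unique(x$covariates$school_id)), x$grid$m,
    if (!is.null(x$truth)) " (simulated, truth attached)" else ""
  ))
  invisible(x)
}
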