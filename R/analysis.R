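#' Configuration for a full four-model analysis
#'
#' @param input Path to a study CSV (see [read_study_csv()]), or `NULL` to
#'   simulate a study from `truth`.
#' @param truth An [simulation_truth()] used when `input` is `NULL`.
#' @param quantiles Quantile levels for the QMEM/FQMEM (default the study
#'   set: 0.10, 0.25, 0.50, 0.85, 0.95, 0.99).
#' @param G_range Candidate basis counts for AIC selection (default 4:7).
#' @param degree Spline degree (default 3).
#' @param B Bootstrap replicates per model (default 1000; >= 50).
#' @param level Pointwise band level (default 0.95).
#' @param seed Master seed; every random step in the run derives from it.
#' @param out_dir Output directory for the report files.
#' @param scheme Bootstrap resampling scheme (see
#'   [bootstrap_functional_inference()]).
#' @param covariates Scalar adjustment covariates.
#' @param n_nodes Quadrature nodes for the quantile engine.
#' @return An object of class `sdee_config`.
#' @export
analysis_config <- function(input = NULL,
                            truth = simulation_truth(),
                            quantiles = c(0.10, 0.25, 0.50, 0.85, 0.95, 0.99),
                            G_range = 4:7,
                            degree = 3L,
                            B = 1000L,
                            level = 0.95,
                            seed = 1L,
                            out_dir = "funqee-report",
                            scheme = "nonparametric",
                            covariates = c("age", "sex", "race", "desk"),
                            n_nodes = 11L) {
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop("quantiles must lie strictly in (0, 1)")
  }
  if (B < 50L) stop("B must be >= 50")
  structure(
    list(input = input, truth = truth, quantiles = quantiles,
         G_range = as.integer(G_range), degree = as.integer(degree),
         B = as.integer(B), level = level, seed = as.integer(seed),
         out_dir = out_dir, scheme = scheme, covariates = covariates,
         n_nodes = as.integer(n_nodes)),
    class = "sdee_config"
  )
}

# bootstrap se/p for a scalar-exposure fit (LMEM-style or QMEM-style),
# stratified subject resampling with replacement as in the band bootstrap
boot_scalar_se <- function(study, fit_fun, B, seed, scheme = "nonparametric") {
  set.seed(seed)
  fit0 <- fit_fun(study)
  coef0 <- ffit_coefs(fit0)
  strata <- split(seq_len(study$n), study$covariates$school_id)
  est <- matrix(NA_real_, length(coef0), B,
                dimnames = list(names(coef0), NULL))
  ok <- logical(B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(strata, function(s) {
      sample(s, length(s), replace = scheme == "nonparametric")
    }), use.names = FALSE)
    fb <- tryCatch(fit_fun(resample_study(study, idx)),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    est[, b] <- ffit_coefs(fb)[names(coef0)]
    ok[b] <- TRUE
  }
  list(fit = fit0,
       table = band_covariate_table(coef0, est[, ok, drop = FALSE]),
       n_fail = B - sum(ok))
}

#' Run the complete four-model analysis and write report files
#'
#' Reads or simulates a study, then fits (1) the LMEM and (2) the QMEM at
#' each configured quantile with the overall mean SDEE as exposure, and
#' (3) the FMEM and (4) the FQMEM at each quantile with the curve entering
#' through AIC-selected B-spline scores, running the stratified subject
#' bootstrap for the functional bands and for QMEM/FMEM/FQMEM coefficient
#' standard errors. All randomness derives from `config$seed`, so the same
#' configuration always produces byte-identical report files. Files are
#' staged in a temporary directory and moved into `config$out_dir` at the
#' end. A model that errors is recorded in `failures.csv` instead of
#' aborting the run.
#'
#' Output files: `descriptives.csv`, `lmem.csv` (model-based SEs),
#' `qmem.csv` (bootstrap SEs, one block per tau), `fmem_coefficients.csv`,
#' `fmem_band.csv`, `fqmem_coefficients.csv`, `fqmem_band.csv`,
#' `aic_selection.csv`, `run_metadata.json`, and `failures.csv` when
#' needed.
#'
#' @param config An [analysis_config()].
#' @return An object of class `sdee_report` (invisibly): all fit objects,
#'   tables, bands, warnings, and the output directory.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "sdee_config"))
  set.seed(config$seed)
  n_seeds <- 4L + 2L * length(config$quantiles)
  seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  study <- if (is.null(config$input)) {
    simulate_study(config$truth, seed = next_seed())
  } else {
    next_seed() # keep the seed stream identical either way
    read_study_csv(config$input)
  }

  report <- list(config = config, study = study, models = list(),
                 failures = list(), warnings = list())
  fail <- function(model, tau, e) {
    report$failures[[length(report$failures) + 1L]] <<- data.frame(
      model = model, tau = if (is.null(tau)) NA_real_ else tau,
      error = conditionMessage(e), stringsAsFactors = FALSE)
  }

  descriptives <- describe_study(study)

  # --- LMEM: scalar exposure, model-based (information) SEs -------------
  lmem_out <- tryCatch({
    design <- build_design(study, "mean", covariates = config$covariates)
    fit_lmem(design$y, design$X, design$cluster, "ML")
  }, error = function(e) { fail("lmem", NULL, e); NULL })
  next_seed() # reserved for the LMEM (keeps the stream stable)

  # --- QMEM at each tau: scalar exposure, bootstrap SEs -----------------
  qmem_out <- list()
  for (tau in config$quantiles) {
    s <- next_seed()
    qmem_out[[as.character(tau)]] <- tryCatch({
      fit_fun <- function(st) {
        d <- build_design(st, "mean", covariates = config$covariates)
        fit_qmem(d$y, d$X, d$cluster, tau, n_nodes = config$n_nodes)
      }
      boot_scalar_se(study, fit_fun, config$B, s, config$scheme)
    }, error = function(e) { fail("qmem", tau, e); NULL })
  }

  # --- FMEM: AIC-selected G, bootstrap band ------------------------------
  aic_rows <- list()
  fmem_out <- tryCatch({
    sel <- select_G_by_aic(study, "fmem", config$G_range,
                           degree = config$degree,
                           covariates = config$covariates)
    aic_rows[[length(aic_rows) + 1L]] <- cbind(model = "fmem",
                                               tau = NA_real_,
                                               sel$aic_table,
                                               selected = sel$aic_table$G == sel$G)
    band <- bootstrap_functional_inference(
      study, function(st) fit_fmem(st, G = sel$G, degree = config$degree,
                                   covariates = config$covariates),
      B = config$B, level = config$level, scheme = config$scheme,
      seed = next_seed())
    list(G = sel$G, band = band)
  }, error = function(e) { fail("fmem", NULL, e); next_seed(); NULL })

  # --- FQMEM at each tau: per-tau AIC-selected G, bootstrap band --------
  fqmem_out <- list()
  for (tau in config$quantiles) {
    s <- next_seed()
    fqmem_out[[as.character(tau)]] <- tryCatch({
      sel <- select_G_by_aic(study, "fqmem", config$G_range, tau = tau,
                             degree = config$degree,
                             covariates = config$covariates,
                             n_nodes = config$n_nodes)
      aic_rows[[length(aic_rows) + 1L]] <- cbind(model = "fqmem", tau = tau,
                                                 sel$aic_table,
                                                 selected = sel$aic_table$G == sel$G)
      band <- bootstrap_functional_inference(
        study, function(st) fit_fqmem(st, tau = tau, G = sel$G,
                                      degree = config$degree,
                                      covariates = config$covariates,
                                      n_nodes = config$n_nodes),
        B = config$B, level = config$level, scheme = config$scheme,
        seed = s)
      list(G = sel$G, band = band)
    }, error = function(e) { fail("fqmem", tau, e); NULL })
  }

  n_models <- 2L + 2L * length(config$quantiles)
  n_failed <- length(report$failures)
  if (n_failed >= n_models) stop("all configured models failed")

  report$descriptives <- descriptives
  report$lmem <- lmem_out
  report$qmem <- qmem_out
  report$fmem <- fmem_out
  report$fqmem <- fqmem_out
  report$aic_table <- if (length(aic_rows)) do.call(rbind, aic_rows) else NULL
  class(report) <- "sdee_report"

  write_report(report, config$out_dir)
  invisible(report)
}

band_table <- function(band, tau = NULL) {
  df <- data.frame(t = band$points, estimate = band$estimate,
                   lower = band$lower, upper = band$upper,
                   excludes_zero = band$lower > 0 | band$upper < 0)
  if (!is.null(tau)) df <- cbind(tau = tau, df)
  df
}

write_report <- function(report, out_dir) {
  staging <- tempfile("funqee-report-")
  dir.create(staging)
  wcsv <- function(df, file) {
    utils::write.csv(df, file.path(staging, file), row.names = FALSE)
  }
  config <- report$config

  wcsv(report$descriptives, "descriptives.csv")

  if (!is.null(report$lmem)) {
    f <- report$lmem
    wcsv(f$coefficients, "lmem.csv")
  }
  if (length(report$qmem)) {
    rows <- lapply(names(report$qmem), function(tn) {
      q <- report$qmem[[tn]]
      if (is.null(q)) return(NULL)
      cbind(tau = as.numeric(tn), q$table,
            converged = q$fit$converged, aic = q$fit$aic)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) wcsv(rows, "qmem.csv")
  }
  if (!is.null(report$fmem)) {
    wcsv(report$fmem$band$covariate_table, "fmem_coefficients.csv")
    wcsv(band_table(report$fmem$band), "fmem_band.csv")
  }
  if (length(report$fqmem)) {
    ct <- do.call(rbind, lapply(names(report$fqmem), function(tn) {
      q <- report$fqmem[[tn]]
      if (is.null(q)) return(NULL)
      cbind(tau = as.numeric(tn), q$band$covariate_table)
    }))
    bt <- do.call(rbind, lapply(names(report$fqmem), function(tn) {
      q <- report$fqmem[[tn]]
      if (is.null(q)) return(NULL)
      band_table(q$band, tau = as.numeric(tn))
    }))
    if (!is.null(ct)) wcsv(ct, "fqmem_coefficients.csv")
    if (!is.null(bt)) wcsv(bt, "fqmem_band.csv")
  }
  if (!is.null(report$aic_table)) wcsv(report$aic_table, "aic_selection.csv")
  if (length(report$failures)) {
    wcsv(do.call(rbind, report$failures), "failures.csv")
  }

  meta <- list(
    package = "funqee",
    version = as.character(utils::packageVersion("funqee")),
    seed = config$seed,
    quantiles = config$quantiles,
    G_range = config$G_range, degree = config$degree,
    B = config$B, level = config$level, scheme = config$scheme,
    input = if (is.null(config$input)) "simulated" else config$input,
    n = report$study$n,
    lmem = if (!is.null(report$lmem)) list(
      sigma2_school = report$lmem$sigma2_school,
      sigma2_resid = report$lmem$sigma2_resid,
      icc = compute_icc(report$lmem),
      loglik = report$lmem$loglik, aic = report$lmem$aic
    ),
    fmem_G = if (!is.null(report$fmem)) report$fmem$G,
    fqmem_G = lapply(report$fqmem, function(q) if (!is.null(q)) q$G),
    warnings = collect_warnings(report),
    n_failures = length(report$failures)
  )
  meta_path <- file.path(staging, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  meta$config_hash <- unname(tools::md5sum(meta_path))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)
  invisible(out_dir)
}

collect_warnings <- function(report) {
  w <- list()
  for (tn in names(report$qmem)) {
    q <- report$qmem[[tn]]
    if (!is.null(q) && length(q$fit$warnings)) {
      w[[paste0("qmem_", tn)]] <- q$fit$warnings
    }
  }
  for (tn in names(report$fqmem)) {
    q <- report$fqmem[[tn]]
    if (!is.null(q)) {
      ww <- c(q$band$fit$engine$warnings, q$band$warnings)
      if (length(ww)) w[[paste0("fqmem_", tn)]] <- ww
    }
  }
  if (!is.null(report$fmem) && length(report$fmem$band$warnings)) {
    w[["fmem"]] <- report$fmem$band$warnings
  }
  w
}

#' @export
print.sdee_report <- function(x, ...) {
  nq <- length(x$config$quantiles)
  cat(sprintf(
    "<sdee_report> n = %d, %d model slots (1 LMEM, %d QMEM, 1 FMEM, %d FQMEM), %d failure(s)\n",
    x$study$n, 2L + 2L * nq, nq, nq, length(x$failures)))
  cat("written to:", x$config$out_dir, "\n")
  invisible(x)
}

#' Parameter-recovery summary on simulated data
#'
#' Simulates a study from `truth`, fits all four model families, and
#' tabulates estimated against true parameters — a quick check that the
#' pipeline recovers the generator's ground truth.
#'
#' @param truth An [simulation_truth()].
#' @param seed Simulation seed.
#' @param G Basis count for the functional fits (default 7).
#' @param quantiles Quantile levels to include (default 0.5).
#' @return A data.frame with columns `model`, `term`, `truth`, `estimate`.
#' @export
recover_parameters <- function(truth = simulation_truth(), seed = 1L,
                               G = 7L, quantiles = 0.5) {
  study <- simulate_study(truth, seed = seed)
  grid <- study$grid
  beta1 <- eval_beta_fun(truth$beta_fun, grid$points)
  int_b1 <- sum(grid$weights * beta1)
  truth_terms <- c("(Intercept)" = truth$beta0, truth$beta_cov,
                   int_beta1 = int_b1)

  d_mean <- build_design(study, "mean")
  lmem <- fit_lmem(d_mean$y, d_mean$X, d_mean$cluster)
  fmem <- fit_fmem(study, G = G)
  rows <- list()
  add <- function(model, term, tr, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, term = term, truth = tr, estimate = est,
      stringsAsFactors = FALSE)
  }
  lc <- ffit_coefs(lmem)
  for (nm in c("age", "sex", "race", "desk")) {
    add("lmem", nm, truth$beta_cov[[nm]], unname(lc[nm]))
  }
  add("lmem", "icc", truth$icc, compute_icc(lmem))
  fc <- ffit_coefs(fmem)
  for (nm in c("age", "sex", "race", "desk")) {
    add("fmem", nm, truth$beta_cov[[nm]], unname(fc[nm]))
  }
  add("fmem", "int_beta1", int_b1,
      sum(grid$weights * fmem$beta_curve$values))
  for (tau in quantiles) {
    fq <- fit_fqmem(study, tau = tau, G = G)
    qc <- ffit_coefs(fq)
    for (nm in c("age", "sex", "race", "desk")) {
      add(sprintf("fqmem_%.2f", tau), nm, truth$beta_cov[[nm]],
          unname(qc[nm]))
    }
    add(sprintf("fqmem_%.2f", tau), "int_beta1", int_b1,
        sum(grid$weights * fq$beta_curve$values))
  }
  do.call(rbind, rows)
}
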