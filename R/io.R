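sdee_col_names <- function(m) sprintf("sdee_h%02d", seq_len(m))

#' Write a study to wide CSV (plus a ground-truth sidecar)
#'
#' Schema: `subject_id, school_id, age, sex, race, desk, bmi,
#' sdee_h01..sdee_hMM`. When the study carries a simulation truth, a JSON
#' sidecar `<path>.truth.json` records the generator parameters and seed
#' (functions are stored as their values on the grid).
#'
#' @param study An `sdee_study`.
#' @param path Output CSV path.
#' @param sidecar Write the truth sidecar when available (default TRUE).
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path, sidecar = TRUE) {
  stopifnot(inherits(study, "sdee_study"))
  cv <- study$curves
  colnames(cv) <- sdee_col_names(study$grid$m)
  out <- cbind(
    study$covariates[, c("subject_id", "school_id", "age", "sex", "race",
                         "desk", "bmi")],
    as.data.frame(cv, row.names = FALSE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(study$truth)) {
    jsonlite::write_json(
      truth_to_list(study$truth, seed = study$seed),
      paste0(path, ".truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

truth_to_list <- function(truth, seed = truth$seed) {
  grid <- time_grid(truth$m)
  cm <- truth$curve_model
  # normalized shape values on the grid (weighted mean 1)
  cm$template <- unname(curve_moments(cm, grid)$mu / cm$mean_sdee)
  list(
    n = truth$n, n_schools = truth$n_schools, m = truth$m,
    beta0 = truth$beta0, beta_cov = as.list(truth$beta_cov),
    beta_fun = eval_beta_fun(truth$beta_fun, grid$points),
    sigma2_school = truth$sigma2_school, sigma2_resid = truth$sigma2_resid,
    icc = truth$icc, proportions = truth$proportions,
    age_mean_sd = truth$age_mean_sd, curve_model = cm,
    bmi_mean = truth$bmi_mean, bmi_sd = truth$bmi_sd, seed = seed
  )
}

#' Read a study from wide CSV
#'
#' Validates the schema written by [write_study_csv()]. Rows with any
#' missing value are rejected with a row-level message (the analytic
#' contract requires complete SDEE profiles); non-positive BMI or unknown
#' category levels abort with the offending field named.
#'
#' @param path CSV path.
#' @param m Expected number of SDEE columns (default 30).
#' @return An `sdee_study` (no truth attached).
#' @export
read_study_csv <- function(path, m = 30L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "school_id", "age", "sex", "race", "desk", "bmi",
            sdee_col_names(m))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema mismatch: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  incomplete <- !stats::complete.cases(df)
  if (any(incomplete)) {
    message(sum(incomplete), " row(s) rejected for missing values: rows ",
            paste(which(incomplete), collapse = ", "))
    df <- df[!incomplete, , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete rows left after filtering")
  if (any(df$bmi <= 0)) {
    stop("field 'bmi': values must be positive (rows ",
         paste(which(df$bmi <= 0), collapse = ", "), ")")
  }
  check_levels <- function(field, levels) {
    bad <- setdiff(unique(df[[field]]), levels)
    if (length(bad)) {
      stop("field '", field, "': unknown levels ",
           paste(bad, collapse = ", "), " (expected ",
           paste(levels, collapse = "/"), ")")
    }
  }
  check_levels("sex", c("boy", "girl"))
  check_levels("race", c("white", "non-white"))
  check_levels("desk", c("stand-biased", "traditional"))
  covariates <- df[, c("subject_id", "school_id", "age", "sex", "race",
                       "desk", "bmi")]
  covariates$log_bmi <- log(covariates$bmi)
  curves <- as.matrix(df[, sdee_col_names(m)])
  if (!is.numeric(curves)) stop("SDEE columns must be numeric")
  new_study(time_grid(m), covariates, curves)
}

#' Descriptive statistics of a study
#'
#' Mean (sd) of BMI, per-subject overall mean SDEE and age, and counts with
#' percentages for desk assignment, race and sex. With a single subject the
#' sd is undefined and reported as `NA`.
#'
#' @param study An `sdee_study` (or any list with `covariates`, `curves`,
#'   `grid` fields).
#' @return A data.frame with columns `variable`, `mean_or_n`, `sd_or_pct`.
#' @export
describe_study <- function(study) {
  cv <- study$covariates
  n <- nrow(cv)
  msd <- function(x) c(mean(x), if (n > 1) stats::sd(x) else NA_real_)
  cnt <- function(flag) c(sum(flag), 100 * mean(flag))
  sdee <- summarize_scalar_sdee(study$curves, study$grid)
  rows <- rbind(
    "BMI (kg/m^2)" = msd(cv$bmi),
    "Average SDEE (cal/min)" = msd(sdee),
    "Age (years)" = msd(cv$age),
    "Stand-biased desks" = cnt(cv$desk == "stand-biased"),
    "Traditional desks" = cnt(cv$desk == "traditional"),
    "White" = cnt(cv$race == "white"),
    "Non-white" = cnt(cv$race == "non-white"),
    "Boys" = cnt(cv$sex == "boy"),
    "Girls" = cnt(cv$sex == "girl")
  )
  data.frame(variable = rownames(rows), mean_or_n = rows[, 1],
             sd_or_pct = rows[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}
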