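read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Build a simulation truth from a plain list
#'
#' Accepts the fields of [simulation_truth()] as a named list — the shape
#' produced by a YAML/JSON config file or by the truth sidecar of
#' [write_study_csv()]. `beta_fun` and `curve_model$template` may be
#' numeric vectors on the grid. Unknown fields are an error so that config
#' typos fail loudly.
#'
#' @param x Named list of truth fields (possibly empty).
#' @return An `sdee_truth`.
#' @export
truth_from_list <- function(x) {
  if (is.null(x)) x <- list()
  allowed <- c("n", "n_schools", "m", "beta0", "beta_cov", "beta_fun",
               "icc", "sigma2_school", "sigma2_resid", "proportions",
               "age_mean_sd", "curve_model", "bmi_mean", "bmi_sd", "seed")
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown truth field(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(x$beta_cov)) x$beta_cov <- unlist(x$beta_cov)
  if (!is.null(x$proportions)) x$proportions <- as.list(x$proportions)
  if (!is.null(x$curve_model)) x$curve_model <- as.list(x$curve_model)
  do.call(simulation_truth, x)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Top-level fields mirror [analysis_config()]; a `truth` sub-object (for
#' simulated input) is passed through [truth_from_list()].
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @param ... Overrides applied after the file (e.g. `seed`, `out_dir`).
#' @return An `sdee_config`.
#' @export
load_analysis_config <- function(path = NULL, ...) {
  x <- if (is.null(path)) list() else read_config_file(path)
  overrides <- list(...)
  x[names(overrides)] <- overrides
  if (!is.null(x$truth) && !inherits(x$truth, "sdee_truth")) {
    x$truth <- truth_from_list(x$truth)
  }
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, x)
}
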