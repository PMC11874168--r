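#' Overall mean SDEE of a curve
#'
#' The scalar summary used by the LMEM and QMEM: the quadrature-weighted
#' mean of the curve over the school day, which under the default
#' equal-weight rectangle rule is the arithmetic mean of the hourly values.
#'
#' @param curve Numeric vector of length `grid$m` or an `n x m` matrix.
#' @param grid The [time_grid()] the curve lives on.
#' @return A scalar (or length-`n` vector) of mean SDEE values, cal/min.
#' @export
summarize_scalar_sdee <- function(curve, grid) {
  validate_grid(grid)
  if (is.matrix(curve)) {
    if (ncol(curve) != grid$m) stop("curve/grid length mismatch")
    if (ncol(curve) == 0L) stop("empty curve")
    return(as.numeric(curve %*% grid$weights))
  }
  if (length(curve) == 0L) stop("empty curve")
  if (length(curve) != grid$m) stop("curve/grid length mismatch")
  sum(curve * grid$weights)
}

#' Build a model design from a study
#'
#' Assembles the response, fixed-effects design matrix and cluster factor
#' for any of the four model families. The SDEE exposure enters either as
#' the scalar overall mean (`sdee = "mean"`, columns `mean_sdee`) or as
#' integrated B-spline scores (`sdee = "scores"`, columns `c1..cG`).
#' Categorical covariates use the contrasts boy vs girl, white vs
#' non-white, stand-biased vs traditional desk (reference level 0).
#'
#' @param study An `sdee_study`.
#' @param sdee `"mean"` or `"scores"`.
#' @param basis Required when `sdee = "scores"`: an
#'   [build_bspline_basis()] object.
#' @param covariates Character vector of scalar covariates to adjust for
#'   (subset of `age`, `sex`, `race`, `desk`).
#' @return List with `y`, `X` (including an `(Intercept)` column),
#'   `cluster` (factor) and `sdee_cols` (names of the exposure columns).
#' @export
build_design <- function(study, sdee = c("mean", "scores"), basis = NULL,
                         covariates = c("age", "sex", "race", "desk")) {
  stopifnot(inherits(study, "sdee_study"))
  sdee <- match.arg(sdee)
  if (sdee == "mean") {
    E <- cbind(mean_sdee = summarize_scalar_sdee(study$curves, study$grid))
  } else {
    if (is.null(basis)) stop("sdee = 'scores' needs a basis")
    E <- score_functional_covariate(study$curves, study$grid, basis)
  }
  Xc <- encode_covariates(study$covariates)
  bad <- setdiff(covariates, colnames(Xc))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  X <- cbind("(Intercept)" = 1, E, Xc[, covariates, drop = FALSE])
  list(y = study$covariates$log_bmi, X = X,
       cluster = factor(study$covariates$school_id),
       sdee_cols = colnames(E))
}

#' Fit a linear mixed model with one cluster random intercept
#'
#' Maximum (or restricted maximum) likelihood estimation of
#' \deqn{y = X\beta + b_{j} + \varepsilon, \quad b_j \sim N(0,\sigma_j^2),
#'   \ \varepsilon \sim N(0,\sigma^2),}
#' by profiling \eqn{\beta} and \eqn{\sigma^2} out of the likelihood and
#' optimizing the one-dimensional profile over the log variance ratio
#' \eqn{\lambda = \sigma_j^2/\sigma^2}. Per-cluster sufficient statistics
#' make each profile evaluation O(J p^2), so fits cost microseconds to
#' milliseconds regardless of n. Standard errors come from the inverse
#' GLS information; p-values are Wald-z (with only a handful of clusters,
#' denominator degree-of-freedom corrections are ill-defined).
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (include the intercept column).
#' @param cluster Cluster identifier (coerced to factor); >= 2 clusters.
#' @param method `"ML"` (default; AIC comparisons across models need ML) or
#'   `"REML"`.
#' @return An object of class `sdee_lmem`: `coefficients` (data.frame with
#'   `estimate`, `se`, `z`, `p`), `sigma2_school`, `sigma2_resid`,
#'   `loglik` (for `method`), `loglik_ml`, `aic` (ML-based,
#'   `2 (p + 2) - 2 logL`), `lambda`, `method`, `n`, `converged`.
#' @export
fit_lmem <- function(y, X, cluster, method = c("ML", "REML")) {
  method <- match.arg(method)
  cluster <- factor(cluster)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || length(cluster) != n) stop("y, X, cluster lengths differ")
  if (nlevels(cluster) < 2L) stop("need >= 2 clusters")
  if (n <= p) stop("more fixed-effect parameters than observations")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is singular; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  ss <- lmem_suffstats(y, X, cluster)
  prof <- function(loglam) lmem_profile(exp(loglam), ss, method)$objective

  # candidate starts: no clustering, the ANOVA moment estimator, and a
  # bounded 1-D search on the log variance ratio
  lam_anova <- max(lmem_anova_lambda(y, X, cluster), 0)
  cand <- c(-Inf, if (lam_anova > 0) log(lam_anova))
  opt <- stats::optimize(prof, interval = c(-25, 15), maximum = TRUE,
                         tol = 1e-10)
  cand_obj <- vapply(cand, function(l) prof(max(l, -700)), numeric(1))
  if (opt$objective >= max(cand_obj)) {
    lambda <- exp(opt$maximum)
  } else {
    lambda <- exp(max(cand[which.max(cand_obj)], -700))
    if (!is.finite(lambda)) lambda <- 0
  }
  fit <- lmem_profile(lambda, ss, method)
  loglik_ml <- if (method == "ML") fit$objective else {
    opt_ml <- stats::optimize(function(l) lmem_profile(exp(l), ss, "ML")$objective,
                              interval = c(-25, 15), maximum = TRUE, tol = 1e-10)
    max(opt_ml$objective, lmem_profile(0, ss, "ML")$objective)
  }

  se <- sqrt(diag(fit$sigma2 * solve(fit$A)))
  z <- fit$beta / se
  coefficients <- data.frame(
    term = colnames(X), estimate = fit$beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefficients,
         sigma2_school = lambda * fit$sigma2,
         sigma2_resid = fit$sigma2,
         lambda = lambda,
         loglik = fit$objective,
         loglik_ml = loglik_ml,
         aic = 2 * (p + 2) - 2 * loglik_ml,
         method = method, n = n, p = p,
         cluster_levels = levels(cluster),
         converged = TRUE),
    class = "sdee_lmem"
  )
}

lmem_suffstats <- function(y, X, cluster) {
  idx <- split(seq_along(y), cluster)
  J <- length(idx)
  p <- ncol(X)
  XtX <- array(0, c(p, p, J)); Xt1 <- matrix(0, p, J)
  Xty <- matrix(0, p, J); oty <- numeric(J); yty <- numeric(J)
  nj <- lengths(idx)
  for (j in seq_len(J)) {
    Xj <- X[idx[[j]], , drop = FALSE]; yj <- y[idx[[j]]]
    XtX[, , j] <- crossprod(Xj)
    Xt1[, j] <- colSums(Xj)
    Xty[, j] <- crossprod(Xj, yj)
    oty[j] <- sum(yj)
    yty[j] <- sum(yj^2)
  }
  list(XtX = XtX, Xt1 = Xt1, Xty = Xty, oty = oty, yty = yty,
       nj = nj, n = length(y), p = p, J = J,
       XtX_tot = apply(XtX, c(1, 2), sum), Xty_tot = rowSums(Xty),
       yty_tot = sum(yty))
}

# profile (restricted) log-likelihood at variance ratio lambda, with the
# GLS beta and profiled sigma^2
lmem_profile <- function(lambda, ss, method) {
  cj <- lambda / (1 + ss$nj * lambda)
  A <- ss$XtX_tot
  b <- ss$Xty_tot
  for (j in seq_len(ss$J)) {
    if (cj[j] > 0) {
      A <- A - cj[j] * tcrossprod(ss$Xt1[, j])
      b <- b - cj[j] * ss$Xt1[, j] * ss$oty[j]
    }
  }
  beta <- solve(A, b)
  rss <- ss$yty_tot - 2 * sum(beta * ss$Xty_tot) +
    drop(crossprod(beta, ss$XtX_tot %*% beta))
  if (any(cj > 0)) {
    r1 <- ss$oty - drop(crossprod(ss$Xt1, beta)) # per-cluster sum of residuals
    rss <- rss - sum(cj * r1^2)
  }
  rss <- max(rss, .Machine$double.xmin)
  logdet <- sum(log1p(ss$nj * lambda))
  n <- ss$n; p <- ss$p
  if (method == "ML") {
    sigma2 <- rss / n
    obj <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  } else {
    sigma2 <- rss / (n - p)
    obj <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
                     determinant(A, logarithm = TRUE)$modulus[1] + (n - p))
  }
  list(objective = obj, beta = beta, sigma2 = sigma2, A = A, rss = rss)
}

# one-way ANOVA moment estimator of lambda on OLS residuals (starting point)
lmem_anova_lambda <- function(y, X, cluster) {
  r <- stats::lm.fit(X, y)$residuals
  nj <- tabulate(cluster)
  rbar <- tapply(r, cluster, mean)
  J <- length(nj); n <- length(r)
  msw <- sum((r - rbar[as.integer(cluster)])^2) / max(n - J, 1)
  msb <- sum(nj * (rbar - mean(r))^2) / max(J - 1, 1)
  k0 <- (n - sum(nj^2) / n) / max(J - 1, 1)
  s2b <- max((msb - msw) / k0, 0)
  if (msw <= 0) return(0)
  s2b / msw
}

#' Intraclass correlation from variance components
#'
#' Share of outcome variance attributable to clusters:
#' \eqn{\sigma_j^2 / (\sigma_j^2 + \sigma^2)}.
#'
#' @param x An `sdee_lmem` fit, or the school variance \eqn{\sigma_j^2}.
#' @param sigma2_resid Residual variance \eqn{\sigma^2} when `x` is numeric.
#' @return The ICC in `[0, 1]`. Errors when both variances are zero.
#' @examples
#' compute_icc(0.001, 0.012) # ~0.0769
#' @export
compute_icc <- function(x, sigma2_resid = NULL) {
  if (inherits(x, "sdee_lmem")) {
    s2b <- x$sigma2_school
    s2e <- x$sigma2_resid
  } else {
    s2b <- x
    s2e <- sigma2_resid
  }
  if (is.null(s2e)) stop("residual variance missing")
  if (s2b < 0 || s2e < 0) stop("variances must be >= 0")
  tot <- s2b + s2e
  if (tot == 0) stop("ICC undefined: both variance components are zero")
  s2b / tot
}

#' @export
print.sdee_lmem <- function(x, digits = 4, ...) {
  cat(sprintf("<sdee_lmem> %s fit, n = %d, logLik = %.3f, AIC = %.3f\n",
              x$method, x$n, x$loglik, x$aic))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("Random effects: school var %.6f, residual var %.6f (ICC %.3f)\n",
              x$sigma2_school, x$sigma2_resid,
              compute_icc(x)))
  invisible(x)
}
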