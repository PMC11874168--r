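# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the basis oracle is a literal Cox-de Boor
# recursion, the variance oracles are closed-form ANOVA moments, and the
# quantile-marginal oracle integrates numerically piece by piece.

# --- Cox-de Boor recursion ------------------------------------------------
deboor_one <- function(i, k, x, knots) {
  if (k == 0) {
    lo <- knots[i]; hi <- knots[i + 1]
    if (x >= lo && x < hi) return(1)
    # close the final half-open interval at the right end of the domain
    if (x == hi && hi == max(knots) && lo < hi) return(1)
    return(0)
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * deboor_one(i, k - 1, x, knots) else 0
  b <- if (d2 > 0) {
    (knots[i + k + 1] - x) / d2 * deboor_one(i + 1, k - 1, x, knots)
  } else 0
  a + b
}

deboor_matrix <- function(t, knots, degree) {
  nb <- length(knots) - degree - 1L
  vapply(seq_len(nb),
         function(i) vapply(t, function(x) deboor_one(i, degree, x, knots),
                            numeric(1)),
         numeric(length(t)))
}

# --- balanced one-way variance-component closed forms ---------------------
anova_oneway <- function(y, cl) {
  k <- length(y) / length(unique(cl))
  J <- length(unique(cl))
  ybarj <- tapply(y, cl, mean)
  MSB <- k * sum((ybarj - mean(y))^2) / (J - 1)
  MSW <- sum((y - ybarj[as.character(cl)])^2) / (J * (k - 1))
  list(MSB = MSB, MSW = MSW,
       reml = c(resid = MSW, school = (MSB - MSW) / k),
       ml = c(resid = MSW, school = ((1 - 1 / J) * MSB - MSW) / k))
}

anova_icc <- function(y, cl) {
  cl <- factor(cl)
  nj <- tabulate(cl)
  J <- nlevels(cl); n <- length(y)
  ybarj <- tapply(y, cl, mean)
  MSB <- sum(nj * (ybarj - mean(y))^2) / (J - 1)
  MSW <- sum((y - ybarj[as.integer(cl)])^2) / (n - J)
  k0 <- (n - sum(nj^2) / n) / (J - 1)
  s2b <- (MSB - MSW) / k0
  s2b / (s2b + MSW)
}

# --- numeric-integration oracle for the QMEM marginal ---------------------
# integrates each cluster's ALD product x Gaussian prior, splitting the
# domain at the check-loss kinks so stats::integrate sees smooth pieces
marginal_loglik_oracle <- function(beta, sigma, sb, y, X, cl, tau) {
  total <- 0
  for (j in unique(cl)) {
    idx <- cl == j
    r <- y[idx] - drop(X[idx, , drop = FALSE] %*% beta)
    brk <- c(min(r) - 12 * max(sb, sigma), sort(r),
             max(r) + 12 * max(sb, sigma))
    fj <- function(b) {
      vapply(b, function(bb) {
        exp(sum(ald_loglik(r, bb, sigma, tau))) * stats::dnorm(bb, 0, sb)
      }, numeric(1))
    }
    v <- 0
    for (k in seq_len(length(brk) - 1L)) {
      v <- v + stats::integrate(fj, brk[k], brk[k + 1], rel.tol = 1e-12,
                                abs.tol = 0)$value
    }
    total <- total + log(v)
  }
  total
}

# --- small simulated fixtures --------------------------------------------
# clustered Gaussian regression data with known coefficients
make_clustered_data <- function(n, J, beta = c(1, 0.5, -0.3),
                                sigma_b = 0.4, sigma = 1, seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(J), length.out = n)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% beta) + rnorm(J, 0, sigma_b)[cl] + rnorm(n, 0, sigma)
  list(y = y, X = X, cl = cl, beta = beta)
}

# tiny default-shaped study for pipeline tests
small_study <- function(n = 96, n_schools = 3, seed = 11, ...) {
  simulate_study(simulation_truth(n = n, n_schools = n_schools, ...),
                 seed = seed)
}

# a band skeleton for significant_windows unit tests
fake_band <- function(lower, upper, m = length(lower)) {
  structure(list(points = seq_len(m) / m, estimate = (lower + upper) / 2,
                 lower = lower, upper = upper),
            class = "sdee_band")
}
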