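#' Common observation grid for energy-expenditure curves
#'
#' Hourly mean school-day energy expenditure (SDEE) is recorded as `m`
#' averages per student; wear time is reparameterized to the unit interval,
#' so hour `k` of `m` sits at `t_k = k/m`. Each hourly mean represents a
#' width-`1/m` slice of the day, giving rectangle-rule quadrature weights
#' `1/m` that sum to one.
#'
#' @param m Number of hourly observations per curve (default 30).
#' @param rule Quadrature rule: `"rectangle"` (default, weights `1/m`) or
#'   `"trapezoid"` (trapezoid weights on the interior grid, extended to
#'   cover `[0, 1]`).
#' @return An object of class `sdee_grid` with fields `m`, `points`
#'   (strictly increasing, in `(0, 1]`) and `weights` (positive, summing
#'   to 1).
#' @examples
#' g <- time_grid(30)
#' sum(g$weights) # 1
#' @export
time_grid <- function(m = 30L, rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  m <- as.integer(m)
  if (is.na(m) || m < 2L) {
    stop("`m` must be an integer >= 2, got ", m)
  }
  points <- seq_len(m) / m
  if (rule == "rectangle") {
    weights <- rep(1 / m, m)
  } else {
    # trapezoid on t_1..t_m plus the two end slices [0,t_1] and nothing
    # beyond t_m = 1; normalized to sum to one
    weights <- c(1.5, rep(1, m - 2L), 0.5) / m
    weights <- weights / sum(weights)
  }
  structure(
    list(m = m, points = points, weights = weights, rule = rule),
    class = "sdee_grid"
  )
}

#' @export
print.sdee_grid <- function(x, ...) {
  cat(sprintf(
    "<sdee_grid> m = %d points on (0,1], %s rule\n", x$m, x$rule
  ))
  invisible(x)
}

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "sdee_grid"))
  if (any(diff(grid$points) <= 0) || any(grid$points <= 0) ||
      any(grid$points > 1)) {
    stop("grid points must be strictly increasing and lie in (0, 1]")
  }
  if (any(grid$weights <= 0) || abs(sum(grid$weights) - 1) > 1e-12) {
    stop("grid weights must be positive and sum to 1")
  }
  invisible(grid)
}
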