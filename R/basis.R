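#' Clamped B-spline basis on the unit interval
#'
#' Builds `G` B-spline basis functions of the given polynomial degree on
#' `[0, 1]` with an open (clamped) knot vector: `degree + 1` repeated
#' boundary knots and `G - degree - 1` equally spaced interior knots. The
#' clamped basis is nonnegative, has local support, and forms a partition of
#' unity (the functions sum to one everywhere), which makes integrated
#' functional scores easy to reason about. With `G = degree + 1` there are
#' no interior knots and the basis reduces to the Bernstein polynomials.
#'
#' @param G Number of basis functions; must satisfy `G >= degree + 1`.
#' @param degree Polynomial degree (default 3, cubic).
#' @param grid Optional [time_grid()]; when given, the `m x G` evaluation
#'   matrix on the grid points is attached as `eval_matrix`.
#' @return An object of class `sdee_basis` with fields `G`, `degree`,
#'   `knots` (full clamped knot vector) and, if `grid` was supplied,
#'   `eval_matrix` and `grid`.
#' @examples
#' b <- build_bspline_basis(4, 3)
#' rowSums(eval_basis(b, c(0, 0.3, 1))) # all 1
#' @export
build_bspline_basis <- function(G, degree = 3L, grid = NULL) {
  G <- as.integer(G); degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0")
  if (G < degree + 1L) {
    stop("G must be at least degree + 1 = ", degree + 1L,
         " basis functions; got G = ", G)
  }
  interior <- if (G > degree + 1L) {
    seq(0, 1, length.out = G - degree + 1L)[-c(1L, G - degree + 1L)]
  } else {
    numeric(0)
  }
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  basis <- structure(
    list(G = G, degree = degree, knots = knots),
    class = "sdee_basis"
  )
  if (!is.null(grid)) {
    validate_grid(grid)
    basis$grid <- grid
    basis$eval_matrix <- eval_basis(basis, grid$points)
  }
  basis
}

#' Evaluate a B-spline basis
#'
#' @param basis An [build_bspline_basis()] object.
#' @param t Evaluation points in `[0, 1]`.
#' @return A `length(t) x G` matrix of basis values.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "sdee_basis"))
  if (any(t < 0 | t > 1)) stop("evaluation points must lie in [0, 1]")
  M <- splines::splineDesign(basis$knots, t, ord = basis$degree + 1L,
                             outer.ok = TRUE)
  dimnames(M) <- list(NULL, paste0("c", seq_len(basis$G)))
  M
}

#' @export
print.sdee_basis <- function(x, ...) {
  cat(sprintf(
    "<sdee_basis> G = %d clamped B-splines of degree %d on [0,1] (%d interior knots)\n",
    x$G, x$degree, length(x$knots) - 2L * (x$degree + 1L)
  ))
  invisible(x)
}

#' Integrated B-spline scores of a functional covariate
#'
#' Reduces a curve `Z(t)` observed on the grid to the length-`G` vector of
#' integrals \eqn{Z_g = \int_0^1 Z(t) c_g(t)\,dt}, approximated by the
#' grid's quadrature rule: `Z_g = sum_k w_k Z(t_k) c_g(t_k)`. These scores
#' are the reparameterized functional covariate entering the FMEM/FQMEM
#' design matrix.
#'
#' @param curve Numeric vector of length `grid$m`, or an `n x m` matrix of
#'   curves (one per row).
#' @param grid The [time_grid()] the curve is observed on.
#' @param basis An [build_bspline_basis()] object.
#' @return A length-`G` vector (or `n x G` matrix) of scores.
#' @export
score_functional_covariate <- function(curve, grid, basis) {
  validate_grid(grid)
  stopifnot(inherits(basis, "sdee_basis"))
  C <- basis_on_grid(basis, grid)
  W <- grid$weights * C # m x G, rows scaled by quadrature weights
  if (is.matrix(curve)) {
    if (ncol(curve) != grid$m) {
      stop("curves have ", ncol(curve), " columns but the grid has ", grid$m)
    }
    S <- curve %*% W
  } else {
    if (length(curve) != grid$m) {
      stop("curve has length ", length(curve), " but the grid has ", grid$m)
    }
    S <- drop(curve %*% W)
  }
  S
}

basis_on_grid <- function(basis, grid) {
  if (!is.null(basis$eval_matrix) && !is.null(basis$grid) &&
      identical(basis$grid$points, grid$points)) {
    basis$eval_matrix
  } else {
    eval_basis(basis, grid$points)
  }
}

#' Reconstruct a functional coefficient from spline coefficients
#'
#' Given fitted spline coefficients `gamma`, returns the coefficient curve
#' \eqn{\hat\beta(t) = \sum_g \hat\gamma_g c_g(t)} evaluated at
#' `eval_points`.
#'
#' @param gamma Numeric vector of length `G`.
#' @param basis An [build_bspline_basis()] object.
#' @param eval_points Points in `[0, 1]` at which to evaluate the curve.
#' @return An object of class `sdee_beta_curve` with fields `points`,
#'   `values` and `gamma`.
#' @export
reconstruct_beta <- function(gamma, basis, eval_points) {
  stopifnot(inherits(basis, "sdee_basis"))
  if (length(gamma) != basis$G) {
    stop("gamma has length ", length(gamma), " but the basis has G = ",
         basis$G)
  }
  values <- drop(eval_basis(basis, eval_points) %*% gamma)
  structure(
    list(points = eval_points, values = values, gamma = as.numeric(gamma)),
    class = "sdee_beta_curve"
  )
}

#' @export
print.sdee_beta_curve <- function(x, ...) {
  cat(sprintf(
    "<sdee_beta_curve> %d evaluation points, range [%.4g, %.4g]\n",
    length(x$points), min(x$values), max(x$values)
  ))
  invisible(x)
}
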