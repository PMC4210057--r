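#' B-spline basis on equidistant knots
#'
#' Eilers-Marx style P-spline basis: `n_basis` B-splines of the given degree
#' on equally spaced knots extended `degree` steps beyond `[min(x), max(x)]`.
#' Rows are non-negative and sum to one on the domain (partition of unity).
#'
#' @param x numeric vector of evaluation points.
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree spline degree (default 3, cubic).
#' @param domain optional `c(min, max)` overriding the data range (used to
#'   evaluate a fitted basis on a new grid).
#' @param clamp if `TRUE`, values outside the domain are clamped to the
#'   boundary before evaluation; if `FALSE` (default) they are an error.
#' @return list with `B` (n x n_basis matrix), `knots` (full extended knot
#'   vector), `degree`, `domain`.
#' @export
bspline_basis <- function(x, n_basis = 10L, degree = 3L, domain = NULL,
                          clamp = FALSE) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0")
  if (n_basis < degree + 1L) stop("n_basis must be at least degree + 1")
  if (is.null(domain)) domain <- range(x)
  xmin <- domain[1]; xmax <- domain[2]
  if (xmax <= xmin) stop("x is constant: no domain to place knots on")
  if (any(x < xmin | x > xmax)) {
    if (!clamp) stop("evaluation points outside the basis domain")
    x <- pmin(pmax(x, xmin), xmax)
  }
  dx <- (xmax - xmin) / (n_basis - degree)
  knots <- xmin + dx * ((-degree):n_basis)
  # pin the inner boundaries exactly so x = xmin, xmax are always admissible
  knots[degree + 1L] <- xmin
  knots[n_basis + 1L] <- xmax
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  list(B = B, knots = knots, degree = degree, domain = c(xmin, xmax))
}

#' Second-order random-walk (difference) penalty matrix
#'
#' `K = t(D2) %*% D2` with `D2` the (m-2) x m second-difference operator.
#' `K` is symmetric positive semidefinite with rank `m - 2`; its null space
#' is spanned by constant and linear coefficient vectors, so those shapes
#' are unpenalized.
#'
#' @param m number of basis coefficients (>= 3).
#' @return m x m penalty matrix.
#' @export
rw2_penalty <- function(m) {
  m <- as.integer(m)
  if (m < 3L) stop("rw2 penalty needs at least 3 coefficients")
  D2 <- diff(diag(m), differences = 2L)
  crossprod(D2)
}

#' Build a penalized spline block for one smooth term
#'
#' Bundles the B-spline basis and its RW2 penalty for a model term
#' `f(x)`, optionally already centred (see [apply_sum_to_zero()]).
#'
#' @inheritParams bspline_basis
#' @return An object of class `spline_block`: list with `B`, `K`, `knots`,
#'   `degree`, `domain`, `x`, and (after constraint) `Z`, the
#'   reparameterization matrix.
#' @export
spline_block <- function(x, n_basis = 10L, degree = 3L) {
  bb <- bspline_basis(x, n_basis = n_basis, degree = degree)
  structure(list(B = bb$B, K = rw2_penalty(ncol(bb$B)), knots = bb$knots,
                 degree = bb$degree, domain = bb$domain, x = x, Z = NULL),
            class = "spline_block")
}

#' Centre a spline block by a sum-to-zero constraint
#'
#' Reparameterizes the basis so that the fitted smooth sums to zero over the
#' observed `x` (equivalently, is orthogonal to the intercept), which makes
#' smooth terms identifiable alongside an explicit intercept. The new basis
#' is `B %*% Z` and the penalty `t(Z) %*% K %*% Z`, where `Z` spans the null
#' space of the constraint `colSums(B) %*% beta = 0`.
#'
#' @param block a [spline_block].
#' @param weights optional observation weights for the constraint (defaults
#'   to 1; the constraint is then an unweighted sum over rows).
#' @return the block with `B`, `K` replaced by their constrained versions and
#'   `Z` recorded; one coefficient fewer than before.
#' @export
apply_sum_to_zero <- function(block, weights = NULL) {
  stopifnot(inherits(block, "spline_block"))
  C <- if (is.null(weights)) colSums(block$B) else colSums(block$B * weights)
  Z <- nullspace_transform(C)
  block$B <- block$B %*% Z
  block$K <- crossprod(Z, block$K %*% Z)
  block$K <- (block$K + t(block$K)) / 2
  block$Z <- Z
  block
}

# Orthonormal basis of the null space of a single linear constraint c'b = 0,
# via the QR decomposition of c.
nullspace_transform <- function(constraint) {
  c_ <- matrix(as.numeric(constraint), ncol = 1)
  qr_ <- qr(c_)
  qr.Q(qr_, complete = TRUE)[, -1, drop = FALSE]
}

#' Evaluate a fitted spline block on a new grid
#'
#' @param block a (possibly constrained) [spline_block].
#' @param grid numeric vector inside the fitted domain.
#' @return matrix mapping block coefficients to fitted values at `grid`.
#' @export
spline_block_eval <- function(block, grid) {
  stopifnot(inherits(block, "spline_block"))
  if (any(grid < block$domain[1] | grid > block$domain[2]))
    stop("grid outside the fitted domain")
  B <- splines::splineDesign(block$knots, grid, ord = block$degree + 1L)
  if (!is.null(block$Z)) B <- B %*% block$Z
  B
}
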