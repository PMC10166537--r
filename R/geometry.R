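#' Lorentz (Minkowski) inner product
#'
#' Computes `<x, y> = -x0*y0 + sum_{i>=1} x_i*y_i`, the bilinear form that
#' defines the hyperboloid model: the upper sheet is the set of points with
#' `<x, x> = -1` and positive first ("time-like") coordinate.
#'
#' @param x,y Numeric vectors of equal length (at least 2); the first entry is
#'   the time-like coordinate.
#' @return A single numeric value; symmetric in its arguments.
#' @examples
#' lorentz_inner(c(1, 0, 0), c(1, 0, 0)) # -1: the origin of the sheet
#' @export
lorentz_inner <- function(x, y) {
  if (length(x) != length(y)) {
    stop("lorentz_inner: 'x' and 'y' must have the same length")
  }
  if (length(x) < 2) stop("lorentz_inner: vectors must have length >= 2")
  -x[1] * y[1] + sum(x[-1] * y[-1])
}

#' Project tangent coordinates onto the hyperboloid sheet
#'
#' Lifts a point `p` of the tangent space at the origin onto the upper sheet
#' by recomputing the time-like coordinate: `x0 = sqrt(1 + sum(p^2))`. The
#' result always satisfies `<x, x> = -1` exactly up to rounding.
#'
#' @param p Numeric vector of length `d` (free tangent coordinates).
#' @return Numeric vector of length `d + 1` on the sheet.
#' @seealso [project_down()] for the exact inverse.
#' @export
project_up <- function(p) {
  if (!all(is.finite(p))) stop("project_up: non-finite tangent coordinates")
  c(sqrt(1 + sum(p^2)), p)
}

#' Drop the time-like coordinate of an on-sheet point
#'
#' @param x Numeric vector of length `d + 1` (a point on the sheet).
#' @return The last `d` coordinates, i.e. the tangent representation.
#' @export
project_down <- function(x) {
  x[-1]
}

# rowwise project_up for an n x d matrix: returns n x (d+1)
.project_up_rows <- function(X) {
  cbind(sqrt(1 + rowSums(X^2)), X)
}

#' Geodesic distance on the hyperboloid
#'
#' Distance between two on-sheet points under curvature `kappa < 0`:
#' `d = acosh(-<x, y>) / sqrt(-kappa)`. The `acosh` argument is clamped to
#' `[1, Inf)` to absorb floating-point rounding for near-identical points.
#' Curvature enters only through the `1/sqrt(-kappa)` factor; the sheet itself
#' is fixed at `<x, x> = -1`.
#'
#' @param x,y On-sheet points (numeric vectors of length `d + 1`).
#' @param kappa Negative curvature. `kappa >= 0` is an error; the Euclidean
#'   regime is a separate code path (see [pairwise_distances()]).
#' @return Nonnegative distance; zero iff `x == y`.
#' @export
hyperbolic_distance <- function(x, y, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa >= 0) {
    stop("hyperbolic_distance: 'kappa' must be a single negative number")
  }
  arg <- max(-lorentz_inner(x, y), 1)
  acosh(arg) / sqrt(-kappa)
}

#' Pairwise distances of embedded taxa
#'
#' Distance matrix of `n` taxa stored as tangent coordinates. For
#' `kappa < 0`, rows are projected onto the sheet and the curvature-scaled
#' hyperboloid metric is used; for `kappa = 0` the plain Euclidean metric on
#' the tangent coordinates is used (the flat regime is an explicit branch, not
#' a limit of the hyperbolic formula).
#'
#' @param X Numeric matrix, `n` taxa by `d` tangent dimensions.
#' @param kappa Curvature, `kappa <= 0`.
#' @return Symmetric `n x n` matrix with zero diagonal, carrying `rownames(X)`
#'   as dimnames when present.
#' @export
pairwise_distances <- function(X, kappa) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("pairwise_distances: need at least 2 points")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa > 0) {
    stop("pairwise_distances: 'kappa' must be a single number <= 0")
  }
  D <- cpp_pairwise_distances(X, kappa)
  if (!is.null(rownames(X))) dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Four-point condition violation (Gromov delta)
#'
#' For every quadruple of points, sort the three pair-sums
#' `d(i,j)+d(k,l)`, `d(i,k)+d(j,l)`, `d(i,l)+d(j,k)` as `S1 >= S2 >= S3`; the
#' quadruple's violation is `(S1 - S2)/2`. The returned delta is the maximum
#' over all `choose(n, 4)` quadruples: the minimal delta for which the metric
#' is delta-hyperbolic. Additive (tree) metrics give exactly 0, and delta
#' scales as `1/sqrt(-kappa)` for hyperboloid distances.
#'
#' @param D Symmetric distance matrix with at least 4 points.
#' @return Nonnegative scalar delta.
#' @export
four_point_delta <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4) stop("four_point_delta: need at least 4 points")
  q <- utils::combn(n, 4)
  i <- q[1, ]; j <- q[2, ]; k <- q[3, ]; l <- q[4, ]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  smax <- pmax(s1, s2, s3)
  smin <- pmin(s1, s2, s3)
  smid <- s1 + s2 + s3 - smax - smin
  max((smax - smid) / 2)
}
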