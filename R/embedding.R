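# Embedding a distance matrix into the hyperboloid: strain-based eigen
# initialisation followed by gradient descent on the stress, plus placement of
# a single new taxon into an existing embedding.

#' Embedding configuration
#'
#' @param dimension Embedding dimension `d >= 2`.
#' @param curvature Curvature `kappa`. `kappa = 0` requests are embedded with
#'   `kappa = -1e-10` (a minuscule curvature standing in for the flat limit,
#'   whose metric formula degenerates).
#' @param max_iterations Cap on gradient-descent iterations (default 1000).
#' @param stress_tolerance Stop when the relative stress improvement of an
#'   iteration falls below this (default 1e-8).
#' @return An object of class `hp_embed_config`.
#' @export
embedding_config <- function(dimension = 3, curvature = -1,
                             max_iterations = 1000, stress_tolerance = 1e-8) {
  stopifnot(dimension >= 2, max_iterations >= 1, stress_tolerance >= 0,
            curvature <= 0)
  structure(list(dimension = as.integer(dimension), curvature = curvature,
                 max_iterations = as.integer(max_iterations),
                 stress_tolerance = stress_tolerance),
            class = "hp_embed_config")
}

#' Stress of an embedding against target distances
#'
#' `sum_{i<j} (D_ij - d(x_i, x_j))^2`, each unordered pair counted once, where
#' `d` is the curvature-`kappa` hyperboloid metric on the projected tangent
#' rows (or Euclidean for `kappa = 0`).
#'
#' @param X Tangent coordinate matrix (`n x d`).
#' @param D Target distance matrix (`n x n`).
#' @param kappa Curvature, `<= 0`.
#' @return Nonnegative stress.
#' @export
stress <- function(X, D, kappa) {
  X <- as.matrix(X); D <- as.matrix(D)
  if (nrow(X) != nrow(D) || nrow(D) != ncol(D)) {
    stop("stress: shapes of X and D do not agree")
  }
  E <- cpp_pairwise_distances(X, kappa) - D
  sum(E[upper.tri(E)]^2)
}

# analytic gradient of stress wrt tangent coordinates (kappa < 0)
.stress_grad <- function(U, D, kappa) {
  s <- sqrt(-kappa)
  x0 <- sqrt(1 + rowSums(U^2))
  C <- tcrossprod(x0) - tcrossprod(U) # = -<x_i, x_j>_L
  C[C < 1] <- 1
  dist <- acosh(C) / s
  denom <- sqrt(C^2 - 1)
  W <- matrix(0, nrow(U), nrow(U))
  ok <- denom > 1e-12
  W[ok] <- 2 * (dist[ok] - D[ok]) / (s * denom[ok])
  diag(W) <- 0
  (U / x0) * as.numeric(W %*% x0) - W %*% U
}

#' Embed a distance matrix into hyperbolic space (hydra-style)
#'
#' Two stages. First, a strain-based initialisation: form
#' `A = cosh(sqrt(-kappa) * D)`, take the `d` spatial coordinate vectors from
#' the eigenvectors of the `d` most negative eigenvalues of `A` scaled by
#' `sqrt(max(-lambda, 0))`, and renormalise every point onto the sheet by
#' recomputing its time coordinate. Second, gradient descent on the stress
#' over all tangent coordinates with backtracking line search, stopping at
#' `max_iterations` or when the relative stress improvement drops below
#' `stress_tolerance`. The result never has higher stress than its own
#' initialisation.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param config An [embedding_config()].
#' @param labels Taxon labels (default `rownames(D)`).
#' @return An object of class `hp_embedding`: list with `tangent` (`n x d`
#'   matrix, rownames = labels), `config`, `labels`, and the achieved
#'   `stress`.
#' @export
embed_hydraplus <- function(D, config = embedding_config(),
                            labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("embed_hydraplus: need at least 2 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) || any(D < 0)) {
    stop("embed_hydraplus: D must be symmetric and nonnegative")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  kappa <- config$curvature
  if (kappa == 0) kappa <- -1e-10
  d <- config$dimension
  s <- sqrt(-kappa)

  A <- cosh(s * D)
  eig <- eigen(A, symmetric = TRUE)
  idx <- order(eig$values)[seq_len(min(d, n))]
  U <- eig$vectors[, idx, drop = FALSE]
  U <- sweep(U, 2, sqrt(pmax(-eig$values[idx], 0)), "*")
  if (ncol(U) < d) U <- cbind(U, matrix(0, n, d - ncol(U)))

  cur <- stress(U, D, kappa)
  for (it in seq_len(config$max_iterations)) {
    G <- .stress_grad(U, D, kappa)
    gnorm2 <- sum(G^2)
    if (gnorm2 < 1e-24) break
    step <- 1
    new <- cur
    repeat {
      cand <- U - step * G
      new <- stress(cand, D, kappa)
      if (new <= cur - 1e-4 * step * gnorm2 || step < 1e-14) break
      step <- step / 2
    }
    if (new >= cur) break
    U <- cand
    improved <- (cur - new) / max(cur, .Machine$double.xmin)
    cur <- new
    if (improved < config$stress_tolerance) break
  }
  rownames(U) <- labels
  structure(list(tangent = U, config = config, labels = labels,
                 stress = cur),
            class = "hp_embedding")
}

#' @export
print.hp_embedding <- function(x, ...) {
  cat("<hp_embedding>", nrow(x$tangent), "taxa in", ncol(x$tangent),
      "dimensions, kappa =", x$config$curvature,
      ", stress =", format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' Place a new taxon into an existing embedding
#'
#' Solves for the location `z` of a new point whose curvature-`kappa`
#' distances to `q` known on-sheet points (rows of `S`) are `dstar`. Each
#' distance constraint linearises to `<z_i, z>_L = -cosh(sqrt(-kappa) d*_i)`,
#' i.e. the linear system `S H z = -cosh(sqrt(-kappa) dstar)` with `H` the
#' Lorentz form. The system is solved exactly for `q = d + 1` and by least
#' squares for `q > d + 1`; the raw solution is then returned to the sheet by
#' recomputing its time coordinate from its spatial part.
#'
#' @param S Matrix of `q` on-sheet points (rows, length `d + 1` each).
#' @param dstar Vector of `q` nonnegative target distances.
#' @param kappa Negative curvature.
#' @return An on-sheet point (numeric vector of length `d + 1`).
#' @export
place_taxon <- function(S, dstar, kappa) {
  S <- as.matrix(S)
  q <- nrow(S); dp1 <- ncol(S)
  if (q < dp1) stop("place_taxon: need at least d + 1 reference points")
  if (length(dstar) != q || any(dstar < 0)) {
    stop("place_taxon: dstar must be ", q, " nonnegative distances")
  }
  if (kappa >= 0) stop("place_taxon: 'kappa' must be negative")
  SH <- S
  SH[, 1] <- -SH[, 1]
  rhs <- -cosh(sqrt(-kappa) * dstar)
  z <- tryCatch(qr.solve(SH, rhs), error = function(e) {
    stop("place_taxon: degenerate reference configuration (singular system)")
  })
  project_up(z[-1])
}
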