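# Posterior summaries and analysis instruments: split frequencies, ASDSF,
# tree-length statistics, single-taxon posterior landscape grids, and
# proposal-neighbourhood characterisation.

# canonical split keys for every retained sample of a trace
.trace_split_keys <- function(trace, ref_label = NULL) {
  ref <- ref_label %||% sort(trace$labels)[1]
  lapply(trace$trees, function(tr) .splits_edge(tr$edge, trace$labels, ref))
}

#' Split frequencies of a posterior trace
#'
#' Fraction of retained samples in which each non-trivial split (bipartition)
#' appears.
#'
#' @param trace An `hp_trace`.
#' @param ref_label Reference taxon for canonical split orientation (default:
#'   alphabetically first label, so tables from different traces over the same
#'   taxa are comparable).
#' @return A tibble of class `hp_split_table` with columns `split` and
#'   `frequency`, sorted by decreasing frequency; the number of samples is in
#'   `attr(, "n_samples")`.
#' @export
split_frequencies <- function(trace, ref_label = NULL) {
  stopifnot(inherits(trace, "hp_trace"))
  if (length(trace$trees) == 0) stop("split_frequencies: empty trace")
  keys <- .trace_split_keys(trace, ref_label)
  ns <- length(keys)
  counts <- table(unlist(keys))
  out <- tibble::tibble(split = names(counts),
                        frequency = as.numeric(counts) / ns)
  out <- out[order(-out$frequency, out$split), ]
  attr(out, "n_samples") <- ns
  class(out) <- c("hp_split_table", class(out))
  out
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' Over all splits whose frequency reaches `min_freq` in at least one of the
#' two traces, the across-run sample standard deviation (divisor `n_runs - 1`)
#' of the split's frequencies is averaged. Values below 0.05 conventionally
#' indicate that two runs sample the same split distribution.
#'
#' @param trace_a,trace_b Two `hp_trace` objects over the same taxon set.
#' @param min_freq Inclusion threshold (default 0.10).
#' @return Nonnegative ASDSF. Erroring (rather than returning 0) when no split
#'   qualifies avoids declaring vacuous convergence.
#' @export
asdsf <- function(trace_a, trace_b, min_freq = 0.10) {
  stopifnot(inherits(trace_a, "hp_trace"), inherits(trace_b, "hp_trace"))
  if (!setequal(trace_a$labels, trace_b$labels)) {
    stop("asdsf: traces must share the same taxon set")
  }
  ref <- sort(trace_a$labels)[1]
  fa <- split_frequencies(trace_a, ref_label = ref)
  fb <- split_frequencies(trace_b, ref_label = ref)
  keys <- union(fa$split, fb$split)
  va <- stats::setNames(rep(0, length(keys)), keys)
  vb <- va
  va[fa$split] <- fa$frequency
  vb[fb$split] <- fb$frequency
  qual <- pmax(va, vb) >= min_freq
  if (!any(qual)) {
    stop("asdsf: no split reaches min_freq = ", min_freq, " in either trace")
  }
  mean(apply(cbind(va[qual], vb[qual]), 1, stats::sd))
}

#' Posterior tree-length summary
#'
#' @param trace An `hp_trace`.
#' @return A one-row tibble with the sample `mean`, `median` and `variance` of
#'   the total tree length over retained samples.
#' @export
tree_length_summary <- function(trace) {
  stopifnot(inherits(trace, "hp_trace"))
  tl <- trace$samples$tree_length
  if (length(tl) == 0) stop("tree_length_summary: empty trace")
  tibble::tibble(mean = mean(tl), median = stats::median(tl),
                 variance = if (length(tl) > 1) stats::var(tl) else 0)
}

#' Posterior landscape of one moving taxon
#'
#' Fixes all embedding locations except one and sweeps that taxon over a 2-D
#' lattice of tangent coordinates. At each lattice point the NJ tree is
#' decoded from the hyperbolic distances and three quantities are recorded:
#' the unnormalised log posterior, the Robinson-Foulds distance to the
#' reference tree (the decode at the unperturbed coordinates), and the total
#' tree length. The log-posterior grid maps the piecewise-smooth, multi-modal
#' structure of the decoded posterior; the RF grid shows the topology regions.
#'
#' @param X Tangent coordinates, `n x 2` (the moving taxon's grid is 2-D).
#' @param moving_index Row index of the taxon to move.
#' @param grid Either a two-column matrix/data frame of lattice points, or a
#'   list of two numeric vectors expanded to their Cartesian product.
#' @param Y An [alignment()] with rows matching `rownames(X)` order.
#' @param prior A [prior_config()].
#' @param kappa Curvature (`<= 0`).
#' @return A tibble with columns `x1`, `x2`, `log_joint`, `rf_to_reference`,
#'   `tree_length`.
#' @export
landscape_scan <- function(X, moving_index, grid, Y,
                           prior = prior_config(), kappa = -1) {
  X <- as.matrix(X)
  if (ncol(X) != 2) stop("landscape_scan: X must be n x 2")
  n <- nrow(X)
  if (moving_index < 1 || moving_index > n) {
    stop("landscape_scan: moving_index out of range")
  }
  stopifnot(inherits(Y, "hp_alignment"), n == Y$n)
  if (is.list(grid) && !is.data.frame(grid) && length(grid) == 2) {
    grid <- as.matrix(expand.grid(x1 = grid[[1]], x2 = grid[[2]]))
  } else {
    grid <- as.matrix(grid)
  }
  if (ncol(grid) != 2) stop("landscape_scan: grid must have two columns")
  pat <- .alignment_patterns(Y)
  ref_dec <- cpp_decode_state(X, kappa, pat$codes, pat$weights)
  ref_splits <- .splits_edge(ref_dec$edge, Y$labels)
  m <- nrow(grid)
  lj <- numeric(m); rf <- integer(m); tl <- numeric(m)
  for (i in seq_len(m)) {
    Xi <- X
    Xi[moving_index, ] <- grid[i, ]
    dec <- cpp_decode_state(Xi, kappa, pat$codes, pat$weights)
    lj[i] <- dec$loglik + .state_log_prior(dec$edge_length, Xi, prior)
    sp <- .splits_edge(dec$edge, Y$labels)
    rf[i] <- length(setdiff(sp, ref_splits)) + length(setdiff(ref_splits, sp))
    tl[i] <- sum(dec$edge_length)
  }
  tibble::tibble(x1 = grid[, 1], x2 = grid[, 2], log_joint = lj,
                 rf_to_reference = rf, tree_length = tl)
}

#' Topology spread of Gaussian proposals around an embedding
#'
#' For each proposal scale `s`, draws isotropic Gaussian perturbations of all
#' tangent coordinates (covariance `s^2 I`), decodes the NJ tree, and records
#' the Robinson-Foulds distance to the reference decode. Characterises how far
#' in tree space a single embedding move can reach: distributions shift
#' stochastically upward with the scale.
#'
#' @param X Tangent coordinates (`n x d`).
#' @param scales Numeric vector of nonnegative proposal scales.
#' @param n_draws Draws per scale.
#' @param kappa Curvature (`<= 0`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `scale`, `draw`, `rf`.
#' @export
neighborhood_sample <- function(X, scales, n_draws, kappa = -1, seed = NULL) {
  stopifnot(all(scales >= 0), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  labels <- rownames(X) %||% paste0("t", seq_len(n))
  D <- cpp_pairwise_distances(X, kappa)
  ref <- cpp_nj(D)
  ref_splits <- .splits_edge(ref$edge, labels)
  out <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    rf <- integer(n_draws)
    for (k in seq_len(n_draws)) {
      Xp <- X + matrix(stats::rnorm(n * d, sd = s), n, d)
      dec <- cpp_nj(cpp_pairwise_distances(Xp, kappa))
      sp <- .splits_edge(dec$edge, labels)
      rf[k] <- length(setdiff(sp, ref_splits)) +
        length(setdiff(ref_splits, sp))
    }
    out[[si]] <- tibble::tibble(scale = s, draw = seq_len(n_draws), rf = rf)
  }
  do.call(rbind, out)
}
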