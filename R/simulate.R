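# Synthetic fixtures: random unrooted trees, JC69-evolved alignments, additive
# and perturbed distance matrices. These emulate, at desk scale, the kind of
# short-branch nucleotide datasets the sampler targets.

#' Random unrooted binary tree
#'
#' Topology by sequential random attachment: starting from the 3-taxon star,
#' each further taxon subdivides a uniformly chosen existing edge. This yields
#' the uniform distribution over unrooted binary topologies. Branch lengths
#' are i.i.d. Exponential with the given mean (default 0.1 substitutions/site,
#' the short-tree regime typical of curated benchmark alignments).
#'
#' @param n_taxa Number of tips (`>= 3`).
#' @param branch_mean Mean branch length.
#' @param seed Optional integer seed.
#' @param labels Tip labels (default `t1..tn`).
#' @return A `phylo` tree with `2 n_taxa - 3` edges.
#' @export
random_tree <- function(n_taxa, branch_mean = 0.1, seed = NULL,
                        labels = paste0("t", seq_len(n_taxa))) {
  if (n_taxa < 3) stop("random_tree: need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  ntip <- as.integer(n_taxa)
  # edges as rows (a, b); internal ids ntip+1, ...
  edges <- rbind(c(ntip + 1L, 1L), c(ntip + 1L, 2L), c(ntip + 1L, 3L))
  next_int <- ntip + 2L
  for (tip in seq_len(ntip)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1)
    a <- edges[e, 1]; b <- edges[e, 2]
    v <- next_int
    next_int <- next_int + 1L
    edges <- edges[-e, , drop = FALSE]
    edges <- rbind(edges, c(a, v), c(v, b), c(v, tip))
  }
  len <- stats::rexp(nrow(edges), rate = 1 / branch_mean)
  .build_phylo(edges, len, labels)
}

#' Simulate an alignment under JC69
#'
#' Evolves nucleotide states along the tree: a uniform root state per site at
#' an internal node, then each edge applies the JC69 transition kernel
#' (`p_same = 1/4 + 3/4 exp(-4 t / 3)`). By reversibility the choice of the
#' anchoring node is immaterial. Also accepts 2-tip trees (used to validate
#' the distance correction).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param L Number of sites (`>= 1`).
#' @param seed Optional integer seed.
#' @return An [alignment()] over `tree$tip.label`.
#' @export
simulate_alignment <- function(tree, L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), L >= 1)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  total <- max(tree$edge)
  states <- matrix(0L, total, L)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE)
  # edges of a phylo in cladewise order are parent-before-child
  ord <- order(tree$edge[, 1]) # ensure parents (smaller preorder ids) first
  for (e in ord) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    psame <- 0.25 + 0.75 * exp(-4 * t / 3)
    keep <- stats::runif(L) < psame
    new <- states[p, ]
    nsub <- sum(!keep)
    if (nsub > 0) {
      # jump uniformly among the three other states
      shift <- sample.int(3L, nsub, replace = TRUE)
      new[!keep] <- 1L + (new[!keep] - 1L + shift) %% 4L
    }
    states[v, ] <- new
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(ntip),
                 function(i) paste(bases[states[i, ]], collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  alignment(seqs)
}

#' Additive (tree-metric) distance matrix of a tree
#'
#' Alias of [tree_path_distances()], exposed for fixture building: the result
#' satisfies the four-point condition exactly (delta = 0), so neighbour
#' joining recovers the source tree.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric additive distance matrix.
#' @export
additive_distances <- function(tree) {
  tree_path_distances(tree)
}

#' Perturb a distance matrix with bounded uniform noise
#'
#' Adds independent symmetric uniform noise in `[-amplitude, amplitude]` to
#' each off-diagonal entry, re-symmetrised, clamped at zero, with the zero
#' diagonal preserved. Drives the neighbour-joining robustness-radius checks:
#' perturbations below half the minimum edge never change the decoded
#' topology.
#'
#' @param D Distance matrix.
#' @param amplitude Nonnegative noise amplitude (l-infinity bound).
#' @param seed Optional integer seed.
#' @return Perturbed matrix of the same shape and dimnames.
#' @export
perturb_distances <- function(D, amplitude, seed = NULL) {
  stopifnot(amplitude >= 0)
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(D)
  n <- nrow(D)
  E <- matrix(0, n, n)
  up <- upper.tri(E)
  E[up] <- stats::runif(sum(up), -amplitude, amplitude)
  E <- E + t(E)
  out <- pmax(D + E, 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(D)
  out
}
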