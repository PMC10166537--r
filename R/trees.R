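# Unrooted tree utilities: NJ decoding, path distances, splits, RF, Newick.
# Trees are ape "phylo" objects throughout; internally the MCMC works with raw
# undirected edge lists (as returned by the C++ NJ decoder) and only builds
# phylo objects for user-facing results.

# Build an ape phylo from an undirected edge list (tips 1..ntip, internal ids
# arbitrary > ntip). Roots the representation at the last internal node,
# renumbers internals in preorder (root = ntip + 1) and orients edges
# parent -> child in cladewise order.
.build_phylo <- function(edge, edge_length, labels) {
  ntip <- length(labels)
  total <- max(edge)
  adj <- vector("list", total)
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, edge_length[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, edge_length[e]))
  }
  root <- total
  new_id <- integer(total)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  next_int <- ntip + 1L
  m <- nrow(edge)
  out_edge <- matrix(0L, m, 2)
  out_len <- numeric(m)
  k <- 0L
  # iterative DFS (preorder)
  stack_node <- root
  stack_par <- 0L
  stack_len <- 0
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]
    p <- stack_par[length(stack_par)]
    lv <- stack_len[length(stack_len)]
    stack_node <- stack_node[-length(stack_node)]
    stack_par <- stack_par[-length(stack_par)]
    stack_len <- stack_len[-length(stack_len)]
    if (v > ntip) {
      new_id[v] <- next_int
      next_int <- next_int + 1L
    }
    if (p > 0L) {
      k <- k + 1L
      out_edge[k, ] <- c(new_id[p], v) # child id fixed below if internal
      out_len[k] <- lv
      if (v > ntip) out_edge[k, 2] <- new_id[v]
    }
    nb <- adj[[v]]
    if (!is.null(nb)) {
      keep <- nb[, 1] != p
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb)) {
        ord <- rev(seq_len(nrow(nb)))
        stack_node <- c(stack_node, nb[ord, 1])
        stack_par <- c(stack_par, rep(v, nrow(nb)))
        stack_len <- c(stack_len, nb[ord, 2])
      }
    }
  }
  tr <- list(edge = out_edge, edge.length = out_len,
             tip.label = labels, Nnode = total - ntip)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Decode a neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (Q-matrix agglomeration with the usual
#' branch-length formulas), used here as the decoder from embedding distances
#' to tree space. It is consistent: an additive matrix returns its unique
#' generating topology with exact branch lengths. Two conventions make the
#' decoding deterministic: ties in the Q criterion are broken by the
#' lexicographically smallest index pair, and negative branch-length estimates
#' are clamped to zero.
#'
#' @param D Symmetric distance matrix with zero diagonal, `n >= 3`.
#' @param labels Character vector of taxon labels in row order of `D`;
#'   defaults to `rownames(D)`.
#' @return An unrooted `phylo` tree with `2n - 3` edges.
#' @export
neighbor_joining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor_joining: need at least 3 taxa")
  if (anyNA(D) || any(!is.finite(D))) {
    stop("neighbor_joining: distance matrix contains NaN or non-finite values")
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("neighbor_joining: distance matrix must be symmetric")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (length(labels) != n) stop("neighbor_joining: labels/matrix size mismatch")
  nj <- cpp_nj(D)
  .build_phylo(nj$edge, nj$edge_length, labels)
}

#' Tip-to-tip path distances on a tree
#'
#' Sums of branch lengths along the unique path between every pair of tips.
#' For a tree decoded from an additive matrix this recovers the input exactly.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric matrix in `tree$tip.label` order with zero diagonal.
#' @export
tree_path_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

#' Total tree length
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

# Non-trivial splits from a raw edge list. Returns a character vector of
# canonical keys: the sorted labels of the side NOT containing `ref_label`,
# joined by commas. Used on trace samples without building phylo objects.
.splits_edge <- function(edge, labels, ref_label = labels[1]) {
  ntip <- length(labels)
  if (ntip < 4) return(character(0))
  total <- max(edge)
  # children lists after rooting at the last internal node
  adj <- vector("list", total)
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- total
  # post-order accumulation of descendant tip sets (logical masks)
  parent <- integer(total)
  order <- integer(0)
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  mask <- matrix(FALSE, total, ntip)
  for (idx in rev(seq_along(order))) {
    v <- order[idx]
    if (v <= ntip) {
      mask[v, v] <- TRUE
    }
    p <- parent[v]
    if (p > 0L) mask[p, ] <- mask[p, ] | mask[v, ]
  }
  ref <- match(ref_label, labels)
  if (is.na(ref)) stop("splits: reference taxon '", ref_label, "' not found")
  keys <- character(0)
  for (v in seq_len(total)) {
    if (v <= ntip || v == root) next
    side <- mask[v, ]
    k <- sum(side)
    if (k < 2 || k > ntip - 2) next # trivial
    if (side[ref]) side <- !side
    keys <- c(keys, paste(sort(labels[side]), collapse = ","))
  }
  sort(unique(keys))
}

#' Non-trivial splits (bipartitions) of an unrooted tree
#'
#' Each internal edge induces a bipartition of the taxon set; the `n - 3`
#' non-trivial ones are returned in a canonical form (the side not containing
#' the reference taxon, labels sorted, comma-joined) so that equal splits
#' compare equal across trees.
#'
#' @param tree A `phylo` tree.
#' @param ref_label Taxon defining the canonical orientation; defaults to the
#'   first tip label. Use a common reference when comparing trees whose tip
#'   orders differ.
#' @return Sorted character vector of split keys (empty for `n < 4`).
#' @export
tree_splits <- function(tree, ref_label = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  if (is.null(ref_label)) ref_label <- labels[1]
  .splits_edge(tree$edge, labels, ref_label)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial split sets of two
#' unrooted trees over the same taxa.
#'
#' @param t1,t2 `phylo` trees with identical taxon sets.
#' @return Nonnegative integer; 0 iff the topologies agree.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("rf_distance: trees must share the same taxon set")
  }
  ref <- sort(t1$tip.label)[1]
  s1 <- tree_splits(t1, ref_label = ref)
  s2 <- tree_splits(t2, ref_label = ref)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()].
#'
#' @param path File path; for `read_newick` a Newick file, for `write_newick`
#'   the destination.
#' @param tree A `phylo` tree.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  # format with enough digits that a round trip preserves lengths to 1e-10
  txt <- .newick_string(tree)
  writeLines(txt, path)
  invisible(path)
}

# Newick serialisation with 15 significant digits on branch lengths.
.newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(v, len) {
    if (v <= ntip) {
      lab <- tree$tip.label[v]
    } else {
      rows <- children[[as.character(v)]]
      parts <- vapply(rows, function(e) {
        rec(tree$edge[e, 2], tree$edge.length[e])
      }, character(1))
      lab <- paste0("(", paste(parts, collapse = ","), ")")
    }
    if (is.na(len)) lab else paste0(lab, ":", formatC(len, digits = 15, format = "g"))
  }
  paste0(rec(root, NA_real_), ";")
}
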