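# Sequence data and the probabilistic model: Hamming/JC69 distances, pruning
# likelihood under JC69, Gamma-Dirichlet prior, unnormalised log posterior.

#' Construct a nucleotide alignment
#'
#' An alignment is a set of equal-length nucleotide sequences with unique
#' taxon labels. Characters outside `A, C, G, T` (gaps, ambiguity codes) are
#' retained and treated as fully missing by the likelihood and distance
#' functions.
#'
#' @param sequences Named character vector of sequence strings, or a character
#'   matrix (taxa in rows, sites in columns) with rownames.
#' @param labels Optional labels overriding the names of `sequences`.
#' @return An object of class `hp_alignment` with fields `labels`, `seqs`
#'   (uppercase strings), `n` and `L`.
#' @export
alignment <- function(sequences, labels = NULL) {
  if (is.matrix(sequences)) {
    labels <- labels %||% rownames(sequences)
    sequences <- apply(sequences, 1, paste, collapse = "")
  }
  labels <- labels %||% names(sequences)
  if (is.null(labels)) stop("alignment: sequences must be labelled")
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(labels)) stop("alignment: duplicate taxon labels")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("alignment: sequences must have equal length")
  if (L < 1) stop("alignment: sequences must have at least one site")
  names(sequences) <- labels
  structure(list(labels = labels, seqs = sequences,
                 n = length(labels), L = L),
            class = "hp_alignment")
}

#' @export
print.hp_alignment <- function(x, ...) {
  cat("<hp_alignment>", x$n, "taxa,", x$L, "sites\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an alignment from FASTA or NEXUS
#'
#' @param path File path. Format is auto-detected (a leading `#NEXUS` selects
#'   the NEXUS data-block reader) unless given explicitly.
#' @param format One of `"auto"`, `"fasta"`, `"nexus"`.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_alignment: no such file: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "fasta"
  }
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)
    seqs <- vapply(dat, function(s) paste(s, collapse = ""), character(1))
  } else {
    dat <- ape::read.FASTA(path)
    seqs <- vapply(as.character(dat), function(s) paste(s, collapse = ""),
                   character(1))
  }
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param Y An [alignment()] object.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(Y, path) {
  stopifnot(inherits(Y, "hp_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(Y$n)) {
    writeLines(c(paste0(">", Y$labels[i]), Y$seqs[i]), con)
  }
  invisible(path)
}

# integer codes: 0 missing/ambiguous, 1..4 = A,C,G,T; n x L matrix
.alignment_codes <- function(Y) {
  chars <- strsplit(Y$seqs, "", fixed = TRUE)
  M <- matrix(0L, Y$n, Y$L)
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(Y$n)) {
    v <- map[chars[[i]]]
    v[is.na(v)] <- 0L
    M[i, ] <- v
  }
  rownames(M) <- Y$labels
  M
}

# site-pattern compression: list(codes = n x npat, weights)
.alignment_patterns <- function(Y) {
  M <- .alignment_codes(Y)
  key <- apply(M, 2, paste, collapse = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  list(codes = M[, first, drop = FALSE], weights = as.numeric(tab))
}

#' Pairwise evolutionary distances between aligned sequences
#'
#' Raw Hamming distance is the proportion of differing sites among sites where
#' both sequences are unambiguous nucleotides. The JC69 correction maps a raw
#' proportion `p` to an expected number of substitutions per site,
#' `-(3/4) log(1 - (4/3) p)`; saturated pairs (`p >= 3/4`) are mapped to
#' `max_distance` rather than erroring so that arbitrary alignments embed.
#'
#' @param Y An [alignment()].
#' @param correction `"jc69"` (default) or `"raw_hamming"`.
#' @param max_distance Cap (substitutions/site) for saturated pairs.
#' @return Symmetric matrix in `Y$labels` order.
#' @export
sequence_distances <- function(Y, correction = c("jc69", "raw_hamming"),
                               max_distance = 10) {
  stopifnot(inherits(Y, "hp_alignment"))
  correction <- match.arg(correction)
  if (Y$n < 3) stop("sequence_distances: need at least 3 sequences")
  M <- .alignment_codes(Y)
  n <- Y$n
  D <- matrix(0, n, n, dimnames = list(Y$labels, Y$labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- M[i, ] > 0L & M[j, ] > 0L
      nc <- sum(ok)
      if (nc == 0) {
        stop("sequence_distances: no comparable sites between '",
             Y$labels[i], "' and '", Y$labels[j], "'")
      }
      p <- sum(M[i, ok] != M[j, ok]) / nc
      d <- if (correction == "raw_hamming") {
        p
      } else if (p >= 0.75) {
        max_distance
      } else {
        -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' JC69 transition probabilities
#'
#' Probability that a site is in the same (`p_same`) or any one particular
#' different (`p_diff`) state after evolving for branch length `t` (expected
#' substitutions per site): `p_same = 1/4 + (3/4) exp(-4t/3)`,
#' `p_diff = 1/4 - (1/4) exp(-4t/3)`, so `p_same + 3 p_diff = 1`.
#'
#' @param t Nonnegative branch length.
#' @return Named numeric vector `c(p_same, p_diff)`.
#' @export
jc69_transition_probability <- function(t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("jc69_transition_probability: 't' must be a single nonnegative number")
  }
  e <- exp(-4 * t / 3)
  c(p_same = 0.25 + 0.75 * e, p_diff = 0.25 - 0.25 * e)
}

# reconcile a tree's tips with the alignment rows; returns integer permutation
.match_taxa <- function(tree_labels, Y) {
  idx <- match(tree_labels, Y$labels)
  if (anyNA(idx)) {
    stop("taxon sets do not match: missing ",
         paste(tree_labels[is.na(idx)], collapse = ", "))
  }
  if (length(idx) != Y$n) stop("taxon sets do not match in size")
  idx
}

#' JC69 log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with uniform base frequencies, summed over sites on the
#' log scale. Sites are compressed to patterns; gaps and ambiguity codes
#' contribute all-ones partials (fully missing). By reversibility the result
#' does not depend on which internal node anchors the traversal.
#'
#' @param tree A `phylo` tree whose tips match `Y$labels` (2-tip trees are
#'   handled by the closed form on the total path length).
#' @param Y An [alignment()].
#' @return Log-likelihood (a nonpositive number for any proper alignment).
#' @export
log_likelihood <- function(tree, Y) {
  stopifnot(inherits(tree, "phylo"), inherits(Y, "hp_alignment"))
  ntip <- length(tree$tip.label)
  pat <- .alignment_patterns(Y)
  idx <- .match_taxa(tree$tip.label, Y)
  codes <- pat$codes[idx, , drop = FALSE]
  if (ntip == 2) {
    t <- sum(tree$edge.length)
    e <- exp(-4 * t / 3)
    psame <- 0.25 + 0.75 * e
    pdiff <- 0.25 - 0.25 * e
    ll <- 0
    for (s in seq_along(pat$weights)) {
      a <- codes[1, s]; b <- codes[2, s]
      site <- if (a == 0L && b == 0L) 1
      else if (a == 0L || b == 0L) 0.25
      else if (a == b) 0.25 * psame
      else 0.25 * pdiff
      ll <- ll + pat$weights[s] * log(site)
    }
    return(ll)
  }
  cpp_jc69_loglik(tree$edge, tree$edge.length, codes, pat$weights)
}

#' Prior configuration
#'
#' The default tree prior is uniform over topologies with a Gamma distribution
#' (shape `gamma_shape`, rate `gamma_rate`) on the total tree length and a
#' symmetric Dirichlet (`dirichlet_alpha`) on the branch-length proportions.
#' The alternative `embedding_normal` mode places independent standard Normal
#' densities on every tangent coordinate of the embedding and no tree-based
#' term; it sidesteps the embedding-to-tree change of variables entirely.
#'
#' @param gamma_shape,gamma_rate Gamma parameters on total tree length
#'   (defaults 1 and 0.1: an Exponential(0.1) total length).
#' @param dirichlet_alpha Symmetric Dirichlet concentration on proportions.
#' @param mode `"gamma_dirichlet"` or `"embedding_normal"`.
#' @return An object of class `hp_prior`.
#' @export
prior_config <- function(gamma_shape = 1, gamma_rate = 0.1,
                         dirichlet_alpha = 1,
                         mode = c("gamma_dirichlet", "embedding_normal")) {
  mode <- match.arg(mode)
  stopifnot(gamma_shape > 0, gamma_rate > 0, dirichlet_alpha > 0)
  structure(list(gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 dirichlet_alpha = dirichlet_alpha, mode = mode),
            class = "hp_prior")
}

# fast path on a raw branch-length vector (gamma_dirichlet mode)
.log_prior_lengths <- function(len, prior) {
  if (any(len < 0)) stop("log_prior: negative branch length")
  K <- length(len)
  TL <- sum(len)
  if (TL == 0) return(-Inf)
  p <- len / TL
  a <- prior$dirichlet_alpha
  ldir <- lgamma(K * a) - K * lgamma(a) +
    if (a == 1) 0 else (a - 1) * sum(log(p))
  stats::dgamma(TL, shape = prior$gamma_shape, rate = prior$gamma_rate,
                log = TRUE) + ldir - (K - 1) * log(TL)
}

#' Log prior density of a tree (or embedding)
#'
#' In `gamma_dirichlet` mode, the density over branch lengths implied by a
#' Gamma on the total length `TL` and a Dirichlet on the proportions
#' `p_e = l_e / TL` is evaluated on the branch lengths themselves, which
#' requires the change-of-variables factor `TL^-(K-1)` for `K` edges; omitting
#' it would bias Metropolis-Hastings ratios. The uniform-topology constant is
#' implemented as 0 (it cancels in all ratios over a fixed taxon set).
#' In `embedding_normal` mode the log density is the sum of standard Normal
#' log densities over the tangent coordinates `X` and the tree is ignored.
#'
#' @param tree A `phylo` tree (used in `gamma_dirichlet` mode).
#' @param prior A [prior_config()].
#' @param X Optional tangent coordinate matrix (required for
#'   `embedding_normal`).
#' @return Log prior density.
#' @export
log_prior <- function(tree, prior = prior_config(), X = NULL) {
  stopifnot(inherits(prior, "hp_prior"))
  if (prior$mode == "embedding_normal") {
    if (is.null(X)) stop("log_prior: embedding_normal mode requires X")
    return(sum(stats::dnorm(as.numeric(X), log = TRUE)))
  }
  stopifnot(inherits(tree, "phylo"))
  .log_prior_lengths(tree$edge.length, prior)
}

#' Unnormalised log posterior of a tree
#'
#' `log_likelihood(tree, Y) + log_prior(...)`; the marginal probability of the
#' data is never computed, as Metropolis-Hastings only needs ratios.
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return Unnormalised log posterior.
#' @export
log_joint <- function(tree, Y, prior = prior_config(), X = NULL) {
  log_likelihood(tree, Y) + log_prior(tree, prior, X)
}
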