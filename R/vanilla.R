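# Baseline Metropolis sampler directly in tree space: nearest-neighbour
# interchange (NNI) topology moves plus multiplicative branch-length moves,
# targeting the same JC69 likelihood and Gamma-Dirichlet prior. It shares no
# machinery with the embedding sampler beyond the model evaluators, so it
# serves as an independent reference for posterior summaries.

# one uniformly random NNI neighbour of an undirected edge list; branch
# lengths travel with their subtrees. Every binary tree has exactly 2(n-3)
# NNI neighbours, so the proposal is symmetric.
.nni_move <- function(edge, len, ntip) {
  both_int <- edge[, 1] > ntip & edge[, 2] > ntip
  cand <- which(both_int)
  if (!length(cand)) return(NULL) # n < 4: no internal edge
  e <- cand[sample.int(length(cand), 1)]
  u <- edge[e, 1]; v <- edge[e, 2]
  # pendant edges at u (excluding e) and at v (excluding e)
  at_u <- which((edge[, 1] == u | edge[, 2] == u) & seq_len(nrow(edge)) != e)
  at_v <- which((edge[, 1] == v | edge[, 2] == v) & seq_len(nrow(edge)) != e)
  eu <- at_u[sample.int(2, 1)] # subtree hanging off u to swap
  ev <- at_v[sample.int(2, 1)] # subtree hanging off v to swap
  # endpoints away from u / v
  a <- if (edge[eu, 1] == u) edge[eu, 2] else edge[eu, 1]
  b <- if (edge[ev, 1] == v) edge[ev, 2] else edge[ev, 1]
  edge[eu, ] <- c(u, b)
  edge[ev, ] <- c(v, a)
  list(edge = edge, len = len)
}

#' Baseline tree-space Metropolis sampler
#'
#' A deliberately simple MCMC over (topology, branch lengths): with
#' probability 0.4 an NNI move on a random internal edge (symmetric), with
#' probability 0.4 a multiplicative move on one random branch
#' (`l' = l e^u`, `u ~ U(-0.5, 0.5)`, Hastings log-ratio `u`), otherwise a
#' whole-tree rescaling (`Hastings log-ratio K u`). Targets
#' `log_likelihood + log_prior` under the same JC69/Gamma-Dirichlet model as
#' [run_mcmc()], but moves natively in tree space; useful as an independent
#' reference for split frequencies and tree-length summaries.
#'
#' @param Y An [alignment()].
#' @param generations Number of Metropolis iterations.
#' @param start_tree Optional `phylo` start (default: NJ on JC69 distances).
#' @param prior A [prior_config()] (`gamma_dirichlet` mode).
#' @param n_samples Retained samples, evenly spaced after `warmup`.
#' @param warmup Burn-in generations (discarded).
#' @param seed Integer seed.
#' @return An `hp_trace` (with `states = NULL`; no embedding is involved).
#' @export
run_vanilla_mcmc <- function(Y, generations, start_tree = NULL,
                             prior = prior_config(), n_samples = 1000,
                             warmup = floor(generations / 10), seed = 1) {
  stopifnot(inherits(Y, "hp_alignment"), Y$n >= 4,
            prior$mode == "gamma_dirichlet")
  set.seed(seed)
  ntip <- Y$n
  pat <- .alignment_patterns(Y)
  if (is.null(start_tree)) {
    start_tree <- neighbor_joining(sequence_distances(Y))
  }
  idx <- .match_taxa(start_tree$tip.label, Y)
  # re-express tip ids in alignment order: tree tip t -> alignment row idx[t]
  edge <- start_tree$edge
  remap <- seq_len(max(edge))
  remap[seq_len(ntip)] <- idx
  edge[] <- remap[edge]
  len <- pmax(start_tree$edge.length, 1e-8)
  ll <- cpp_jc69_loglik(edge, len, pat$codes, pat$weights)
  lp <- ll + .log_prior_lengths(len, prior)

  post <- generations - warmup
  sample_gens <- unique(floor(seq(warmup + 1, generations,
                                  length.out = min(n_samples, post))))
  out_trees <- vector("list", length(sample_gens))
  out_lp <- numeric(length(sample_gens))
  out_tl <- numeric(length(sample_gens))
  rec <- 0L; next_sample <- 1L
  n_acc <- 0L
  for (g in seq_len(generations)) {
    kind <- stats::runif(1)
    log_hastings <- 0
    if (kind < 0.4) {
      mv <- .nni_move(edge, len, ntip)
      if (is.null(mv)) next
      edge2 <- mv$edge; len2 <- mv$len
    } else if (kind < 0.8) {
      e <- sample.int(length(len), 1)
      u <- stats::runif(1, -0.5, 0.5)
      len2 <- len; len2[e] <- len[e] * exp(u)
      edge2 <- edge
      log_hastings <- u
    } else {
      u <- stats::runif(1, -0.2, 0.2)
      len2 <- len * exp(u)
      edge2 <- edge
      log_hastings <- length(len) * u
    }
    ll2 <- cpp_jc69_loglik(edge2, len2, pat$codes, pat$weights)
    lp2 <- ll2 + .log_prior_lengths(len2, prior)
    if (log(stats::runif(1)) < lp2 - lp + log_hastings) {
      edge <- edge2; len <- len2; lp <- lp2
      n_acc <- n_acc + 1L
    }
    if (next_sample <= length(sample_gens) && g == sample_gens[next_sample]) {
      rec <- rec + 1L
      out_trees[[rec]] <- list(edge = edge, len = len)
      out_lp[rec] <- lp
      out_tl[rec] <- sum(len)
      next_sample <- next_sample + 1L
    }
  }
  structure(list(
    samples = tibble::tibble(generation = sample_gens,
                             log_joint = out_lp, tree_length = out_tl),
    trees = out_trees,
    states = NULL,
    labels = Y$labels,
    acceptance = tibble::tibble(chain = 1L, beta = 1,
                                proposed = generations, accepted = n_acc,
                                rate = n_acc / generations),
    swaps = c(attempted = 0L, accepted = 0L),
    config = list(sampler = "vanilla", generations = generations,
                  warmup = warmup, seed = seed)
  ), class = "hp_trace")
}
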