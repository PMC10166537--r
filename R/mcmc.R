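# Metropolis-coupled MCMC over embedding states. Every generation proposes a
# joint Gaussian move of all n*d tangent coordinates, decodes the NJ tree from
# the pairwise hyperbolic distances, scores it with the JC69 likelihood and
# the tree prior, and applies a Metropolis step on the tempered log posterior.
# No embedding-to-tree Jacobian term is applied (the decoding map has no
# usable Jacobian: the coordinate-to-distance stage has null determinant and
# neighbour joining is non-differentiable), matching the published algorithm.

#' MCMC configuration
#'
#' Defaults mirror the reference experimental setup: warm-up of 1e4
#' generations tuning an empirical proposal covariance, then robust adaptive
#' Metropolis; four chains with ten swap attempts every 1e3 generations; 1e4
#' evenly spaced retained samples; three embedding dimensions at curvature -1.
#'
#' @param generations Total generations (including warm-up).
#' @param warmup Warm-up generations (empirical covariance tuning).
#' @param n_chains Number of Metropolis-coupled chains; chain `i` runs at
#'   inverse temperature `beta_i = 1 / (1 + temp_lambda (i - 1))`.
#' @param swap_interval Generations between swap rounds.
#' @param swaps_per_interval Swap attempts per round (adjacent pairs).
#' @param n_samples Retained cold-chain samples (evenly spaced post-warm-up).
#' @param curvature Embedding curvature (`< 0`; `0` selects Euclidean mode).
#' @param dimension Embedding dimension.
#' @param seed Integer seed; a fixed seed gives a bit-identical trace.
#' @param start `"nj"` (embed JC69-corrected sequence distances) or
#'   `"given_tree"` (embed path distances of a supplied tree).
#' @param prior A [prior_config()].
#' @param ram_target Target acceptance rate for RAM adaptation.
#' @param temp_lambda Temperature-ladder increment.
#' @return An object of class `hp_mcmc_config`.
#' @export
mcmc_config <- function(generations, warmup = 1e4, n_chains = 4,
                        swap_interval = 1e3, swaps_per_interval = 10,
                        n_samples = 1e4, curvature = -1, dimension = 3,
                        seed = 1, start = c("nj", "given_tree"),
                        prior = prior_config(), ram_target = 0.234,
                        temp_lambda = 0.1) {
  start <- match.arg(start)
  stopifnot(generations >= warmup, warmup >= 0, n_chains >= 1,
            curvature <= 0, dimension >= 2, inherits(prior, "hp_prior"))
  n_samples <- min(n_samples, max(generations - warmup, 1))
  structure(list(generations = as.integer(generations),
                 warmup = as.integer(warmup),
                 n_chains = as.integer(n_chains),
                 swap_interval = as.integer(swap_interval),
                 swaps_per_interval = as.integer(swaps_per_interval),
                 n_samples = as.integer(n_samples),
                 curvature = curvature, dimension = as.integer(dimension),
                 seed = as.integer(seed), start = start, prior = prior,
                 ram_target = ram_target, temp_lambda = temp_lambda),
            class = "hp_mcmc_config")
}

#' Propose a candidate embedding state
#'
#' Draws one joint multivariate Gaussian perturbation of all `n * d` tangent
#' coordinates: `vec(X') = vec(X) + S z`, `z ~ N(0, I)`, with `S` the chain's
#' lower-triangular scale factor (so the proposal covariance is `S S^T`). The
#' density is symmetric in (current, candidate), so no Hastings ratio is
#' needed.
#'
#' @param state A chain state as produced by [run_mcmc()]'s internals: a list
#'   with elements `X` (n x d matrix) and `scale` (nd x nd lower-triangular).
#' @return List with `X` (candidate tangent coordinates) and `z` (the standard
#'   normal increment used, needed by [ram_adapt()]).
#' @export
propose <- function(state) {
  X <- state$X
  nd <- length(X)
  z <- stats::rnorm(nd)
  u <- as.numeric(state$scale %*% z)
  Xc <- X + matrix(u, nrow(X), ncol(X))
  list(X = Xc, z = z)
}

#' Metropolis acceptance probability on a tempered log posterior
#'
#' `min(1, exp(beta * (lp_candidate - lp_current)))`. The proposal is
#' symmetric and no decoding Jacobian is applied, so this is the whole ratio.
#'
#' @param lp_current,lp_candidate Unnormalised log posteriors (the candidate
#'   may be `-Inf`).
#' @param beta Inverse temperature in (0, 1].
#' @return Acceptance probability in [0, 1].
#' @export
accept_probability <- function(lp_current, lp_candidate, beta = 1) {
  if (is.na(lp_candidate) || lp_candidate == -Inf) return(0)
  min(1, exp(beta * (lp_candidate - lp_current)))
}

#' Robust adaptive Metropolis (RAM) scale update
#'
#' Rank-one update of the proposal covariance `S S^T` in the direction of the
#' last standardised increment `z`, with magnitude
#' `eta_i * (accepted_prob - target_rate)`, `eta_i = min(1, dim * i^(-2/3))`.
#' The adaptation steers the empirical acceptance rate toward `target_rate`
#' and diminishes with iteration count, preserving ergodicity. The updated
#' factor stays lower-triangular with positive diagonal.
#'
#' @param scale Lower-triangular scale factor (`nd x nd`).
#' @param z Standard normal increment of the last proposal.
#' @param accepted_prob Acceptance probability of the last proposal.
#' @param iteration Post-warm-up iteration counter (`>= 1`).
#' @param target_rate Target acceptance rate (default 0.234).
#' @return Updated lower-triangular scale factor.
#' @export
ram_adapt <- function(scale, z, accepted_prob, iteration,
                      target_rate = 0.234) {
  stopifnot(iteration >= 1, accepted_prob >= 0, accepted_prob <= 1)
  nd <- nrow(scale)
  eta <- min(1, nd * iteration^(-2 / 3))
  c0 <- eta * (accepted_prob - target_rate)
  if (c0 == 0) return(scale)
  u <- as.numeric(scale %*% z)
  zn2 <- sum(z^2)
  if (zn2 == 0) return(scale)
  M <- tcrossprod(scale) + (c0 / zn2) * tcrossprod(u)
  out <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    warning("ram_adapt: non-finite or indefinite update skipped")
    return(scale)
  }
  out
}

#' Attempt state swaps between adjacent tempered chains
#'
#' Repeats `n_swaps` times: pick a random adjacent temperature pair `(i, j)`
#' and exchange their states with probability
#' `min(1, exp((beta_i - beta_j) * (lp_j - lp_i)))`. Temperatures stay
#' attached to chain slots; only the states (and cached values) move.
#'
#' @param states List of chain states (each with `X`, `edge`, `len`, `lp`, and
#'   `beta`).
#' @param n_swaps Number of swap attempts.
#' @return List with updated `states`, plus `attempted` and `accepted` counts.
#' @export
swap_move <- function(states, n_swaps = 1) {
  k <- length(states)
  acc <- 0L
  if (k < 2) return(list(states = states, attempted = 0L, accepted = 0L))
  for (s in seq_len(n_swaps)) {
    i <- sample.int(k - 1, 1)
    j <- i + 1L
    lr <- (states[[i]]$beta - states[[j]]$beta) *
      (states[[j]]$lp - states[[i]]$lp)
    if (log(stats::runif(1)) < lr) {
      keep <- c("X", "edge", "len", "lp", "loglik")
      tmp <- states[[i]][keep]
      states[[i]][keep] <- states[[j]][keep]
      states[[j]][keep] <- tmp
      acc <- acc + 1L
    }
  }
  list(states = states, attempted = as.integer(n_swaps), accepted = acc)
}

# score a decoded state: log prior from branch lengths (or embedding normal)
.state_log_prior <- function(len, X, prior) {
  if (prior$mode == "embedding_normal") {
    sum(stats::dnorm(as.numeric(X), log = TRUE))
  } else {
    .log_prior_lengths(len, prior)
  }
}

#' Run hyperbolic-embedding MCMC
#'
#' The full sampler: embed the taxa (from JC69-corrected sequence distances,
#' or from the path distances of `start_tree`), then run Metropolis-coupled
#' chains of joint Gaussian tangent-space moves. Every generation re-decodes
#' the neighbour-joining tree from the proposed coordinates and scores it with
#' the JC69 pruning likelihood and the configured prior. During warm-up the
#' proposal covariance is the empirical covariance of the chain's states
#' (scaled by `2.38^2 / (n d)`, refreshed every 100 generations, initialised
#' at `0.01^2 I`); afterwards it is adapted by [ram_adapt()]. Only the cold
#' chain is recorded, thinned to `n_samples` evenly spaced post-warm-up
#' generations.
#'
#' @param Y An [alignment()].
#' @param config An [mcmc_config()].
#' @param start_tree Optional `phylo` start tree (required when
#'   `config$start == "given_tree"`).
#' @return An object of class `hp_trace`: `samples` (tibble with `generation`,
#'   `log_joint`, `tree_length`), `trees` (list of raw edge/length pairs),
#'   `states` (list of tangent matrices), `labels`, `acceptance` (per-chain
#'   tibble), `swaps`, and `config`.
#' @export
run_mcmc <- function(Y, config, start_tree = NULL) {
  stopifnot(inherits(Y, "hp_alignment"), inherits(config, "hp_mcmc_config"))
  if (Y$n < 3) stop("run_mcmc: need at least 3 taxa")
  if (config$start == "given_tree" && is.null(start_tree)) {
    stop("run_mcmc: start = 'given_tree' requires a start_tree")
  }
  set.seed(config$seed)
  kappa <- config$curvature
  n <- Y$n
  d <- config$dimension
  nd <- n * d
  prior <- config$prior
  pat <- .alignment_patterns(Y)

  if (!is.null(start_tree)) {
    idx <- .match_taxa(start_tree$tip.label, Y)
    D0 <- tree_path_distances(start_tree)[Y$labels, Y$labels]
  } else {
    D0 <- sequence_distances(Y, correction = "jc69")
  }
  emb <- embed_hydraplus(
    D0, embedding_config(dimension = d, curvature = kappa), labels = Y$labels
  )
  X0 <- emb$tangent

  betas <- 1 / (1 + config$temp_lambda * (seq_len(config$n_chains) - 1))
  init_state <- function(beta) {
    dec <- cpp_decode_state(X0, kappa, pat$codes, pat$weights)
    lp <- dec$loglik + .state_log_prior(dec$edge_length, X0, prior)
    list(X = X0, edge = dec$edge, len = dec$edge_length,
         loglik = dec$loglik, lp = lp,
         scale = diag(0.01, nd), beta = beta)
  }
  states <- lapply(betas, init_state)

  gens <- config$generations
  warmup <- config$warmup
  post <- gens - warmup
  sample_gens <- if (post >= 1) {
    unique(floor(seq(warmup + 1, gens, length.out = config$n_samples)))
  } else {
    integer(0)
  }
  ns <- max(length(sample_gens), 1L)
  out_gen <- integer(ns); out_lp <- numeric(ns); out_tl <- numeric(ns)
  out_trees <- vector("list", ns); out_states <- vector("list", ns)
  rec <- 0L
  if (post < 1) { # record the decoded start state only
    rec <- 1L
    out_gen[1] <- 0L
    out_lp[1] <- states[[1]]$lp
    out_tl[1] <- sum(states[[1]]$len)
    out_trees[[1]] <- list(edge = states[[1]]$edge, len = states[[1]]$len)
    out_states[[1]] <- states[[1]]$X
  }

  n_prop <- integer(config$n_chains)
  n_acc <- integer(config$n_chains)
  warm_hist <- lapply(seq_len(config$n_chains),
                      function(i) matrix(0, min(warmup, 1e4), nd))
  warm_count <- integer(config$n_chains)
  swap_att <- 0L; swap_acc <- 0L
  next_sample <- 1L

  for (g in seq_len(gens)) {
    in_warm <- g <= warmup
    for (ci in seq_len(config$n_chains)) {
      st <- states[[ci]]
      pr <- propose(st)
      dec <- cpp_decode_state(pr$X, kappa, pat$codes, pat$weights)
      lpc <- dec$loglik + .state_log_prior(dec$edge_length, pr$X, prior)
      a <- accept_probability(st$lp, lpc, st$beta)
      n_prop[ci] <- n_prop[ci] + 1L
      if (stats::runif(1) < a) {
        st$X <- pr$X; st$edge <- dec$edge; st$len <- dec$edge_length
        st$loglik <- dec$loglik; st$lp <- lpc
        n_acc[ci] <- n_acc[ci] + 1L
      }
      if (in_warm) {
        if (warm_count[ci] < nrow(warm_hist[[ci]])) {
          warm_count[ci] <- warm_count[ci] + 1L
          warm_hist[[ci]][warm_count[ci], ] <- as.numeric(st$X)
        }
        if (g %% 100 == 0 && warm_count[ci] > 10) {
          H <- warm_hist[[ci]][seq_len(warm_count[ci]), , drop = FALSE]
          C <- stats::cov(H) * (2.38^2 / nd) + diag(1e-10, nd)
          sc <- tryCatch(t(chol(C)), error = function(e) NULL)
          if (!is.null(sc)) st$scale <- sc
        }
      } else {
        st$scale <- ram_adapt(st$scale, pr$z, a, g - warmup,
                              target_rate = config$ram_target)
      }
      states[[ci]] <- st
    }
    if (config$n_chains > 1 && g %% config$swap_interval == 0) {
      sw <- swap_move(states, config$swaps_per_interval)
      states <- sw$states
      swap_att <- swap_att + sw$attempted
      swap_acc <- swap_acc + sw$accepted
    }
    if (next_sample <= length(sample_gens) && g == sample_gens[next_sample]) {
      rec <- rec + 1L
      cold <- states[[1]]
      out_gen[rec] <- g
      out_lp[rec] <- cold$lp
      out_tl[rec] <- sum(cold$len)
      out_trees[[rec]] <- list(edge = cold$edge, len = cold$len)
      out_states[[rec]] <- cold$X
      next_sample <- next_sample + 1L
    }
  }

  structure(list(
    samples = tibble::tibble(generation = out_gen[seq_len(rec)],
                             log_joint = out_lp[seq_len(rec)],
                             tree_length = out_tl[seq_len(rec)]),
    trees = out_trees[seq_len(rec)],
    states = out_states[seq_len(rec)],
    labels = Y$labels,
    acceptance = tibble::tibble(
      chain = seq_len(config$n_chains), beta = betas,
      proposed = n_prop, accepted = n_acc,
      rate = ifelse(n_prop > 0, n_acc / n_prop, NA_real_)
    ),
    swaps = c(attempted = swap_att, accepted = swap_acc),
    config = config
  ), class = "hp_trace")
}

#' @export
print.hp_trace <- function(x, ...) {
  cat("<hp_trace>", nrow(x$samples), "retained samples,",
      length(x$labels), "taxa\n")
  if (nrow(x$samples) > 0) {
    cat("  log joint: ", format(mean(x$samples$log_joint), digits = 6),
        " (mean), tree length: ",
        format(mean(x$samples$tree_length), digits = 4), " (mean)\n", sep = "")
  }
  invisible(x)
}

#' Extract retained trees from a trace
#'
#' @param trace An `hp_trace`.
#' @return A `multiPhylo` list of the retained samples.
#' @export
trace_trees <- function(trace) {
  stopifnot(inherits(trace, "hp_trace"))
  out <- lapply(trace$trees, function(tr) {
    .build_phylo(tr$edge, tr$len, trace$labels)
  })
  class(out) <- "multiPhylo"
  out
}
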