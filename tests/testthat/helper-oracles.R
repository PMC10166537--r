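# Independent oracles and small fixtures used across the test files.

# hand-built 2-tip tree (for closed-form likelihood / distance checks)
two_tip_tree <- function(t1, t2, labels = c("A", "B")) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(t1, t2), tip.label = labels, Nnode = 1L),
            class = "phylo")
}

# the quartet ((A:1,B:2):1,(C:3,D:4)) as an additive distance matrix
quartet_matrix <- function() {
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, byrow = TRUE)
  dimnames(m) <- rep(list(c("A", "B", "C", "D")), 2)
  m
}

# Brute-force JC69 likelihood: sum over all 4^(n-2) internal-state
# assignments, uniform root distribution. Independent of the pruning code.
oracle_loglik <- function(tree, Y) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(Y$seqs[tree$tip.label], "", fixed = TRUE)
  codes <- t(vapply(chars, function(v) {
    z <- map[v]; z[is.na(z)] <- 0L; z
  }, integer(Y$L)))
  P <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(m) <- 0.25 + 0.75 * e
    m
  }
  Plist <- lapply(tree$edge.length, P)
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  ll <- 0
  for (s in seq_len(Y$L)) {
    site_lik <- 0
    for (g in seq_len(nrow(grid))) {
      st <- grid[g, ]
      lik <- 0.25 # uniform root state probability
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
        sp <- st[p - ntip]
        if (v <= ntip) {
          obs <- codes[v, s]
          lik <- lik * if (obs == 0L) 1 else Plist[[e]][sp, obs]
        } else {
          lik <- lik * Plist[[e]][sp, st[v - ntip]]
        }
        if (lik == 0) break
      }
      site_lik <- site_lik + lik
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# Least-squares quartet fit: for each of the three quartet topologies solve
# the 6 x 5 path system for branch lengths; return the topology (as a split
# key) and lengths with the smallest residual. Independent NJ oracle.
oracle_quartet <- function(D) {
  labs <- rownames(D)
  d6 <- c(D[1, 2], D[1, 3], D[1, 4], D[2, 3], D[2, 4], D[3, 4])
  # columns: pendant a,b,c,d then internal e; rows: AB AC AD BC BD CD
  mk <- function(pairs_with_internal) {
    A <- matrix(0, 6, 5)
    pend <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (r in 1:6) {
      A[r, pend[r, 1]] <- 1
      A[r, pend[r, 2]] <- 1
      if (r %in% pairs_with_internal) A[r, 5] <- 1
    }
    A
  }
  # AB|CD: internal on AC, AD, BC, BD (rows 2:5)
  # AC|BD: internal on AB, AD, BC, CD (rows 1, 3, 4, 6)
  # AD|BC: internal on AB, AC, BD, CD (rows 1, 2, 5, 6)
  tops <- list("AB|CD" = 2:5, "AC|BD" = c(1, 3, 4, 6),
               "AD|BC" = c(1, 2, 5, 6))
  best <- NULL
  for (nm in names(tops)) {
    A <- mk(tops[[nm]])
    fit <- qr.solve(A, d6)
    res <- sum((A %*% fit - d6)^2)
    if (is.null(best) || res < best$res) {
      best <- list(top = nm, lengths = fit, res = res)
    }
  }
  # convert the winning pairing to a canonical split key (side without labs[1])
  side <- switch(best$top,
                 "AB|CD" = labs[3:4],
                 "AC|BD" = labs[c(2, 4)],
                 "AD|BC" = labs[2:3])
  best$split <- paste(sort(side), collapse = ",")
  best
}

# random tree whose branch lengths are uniform on [lo, hi] (controlled
# minimum edge for the NJ radius suites)
random_tree_unif <- function(n, lo = 0.05, hi = 0.5) {
  tr <- random_tree(n)
  tr$edge.length <- stats::runif(length(tr$edge.length), lo, hi)
  tr
}

# tiny 5-taxon study fixture: internal edges set to a given length
study_tree <- function(seed, internal = 0.1) {
  tr <- random_tree(5, seed = seed)
  int <- tr$edge[, 1] > 5 & tr$edge[, 2] > 5
  tr$edge.length[int] <- internal
  tr
}

# a minimal hand-built trace over 4 taxa for the split bookkeeping tests
fake_trace <- function(splits_per_sample, labels = c("A", "B", "C", "D")) {
  # splits_per_sample: character vector, one quartet split key per sample,
  # from c("C,D", "B,D", "B,C") meaning AB|CD, AC|BD, AD|BC resolutions
  mk_edges <- function(key) {
    pairing <- switch(key,
                      "C,D" = c(3L, 4L), "B,D" = c(2L, 4L), "B,C" = c(2L, 3L))
    rest <- setdiff(1:4, pairing)
    edge <- rbind(c(5L, rest[1]), c(5L, rest[2]), c(5L, 6L),
                  c(6L, pairing[1]), c(6L, pairing[2]))
    list(edge = edge, len = rep(0.1, 5))
  }
  trees <- lapply(splits_per_sample, mk_edges)
  structure(list(
    samples = tibble::tibble(
      generation = seq_along(trees),
      log_joint = rep(-1, length(trees)),
      tree_length = vapply(trees, function(t) sum(t$len), numeric(1))
    ),
    trees = trees, states = NULL, labels = labels,
    acceptance = NULL, swaps = c(attempted = 0L, accepted = 0L),
    config = list()
  ), class = "hp_trace")
}
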