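test_that("split frequencies count bipartitions over retained samples", {
  tr <- fake_trace(rep("C,D", 5))
  sf <- split_frequencies(tr)
  expect_equal(sf$split, "C,D")
  expect_equal(sf$frequency, 1)
  tr2 <- fake_trace(c("C,D", "B,D", "C,D", "B,D"))
  sf2 <- split_frequencies(tr2)
  expect_equal(sort(sf2$frequency), c(0.5, 0.5))
  expect_error(split_frequencies(fake_trace(character(0))), "empty")
})

test_that("concatenated traces have sample-size-weighted split frequencies", {
  a <- fake_trace(c("C,D", "C,D", "B,D"))
  b <- fake_trace(rep("B,D", 6))
  both <- fake_trace(c(c("C,D", "C,D", "B,D"), rep("B,D", 6)))
  fa <- split_frequencies(a); fb <- split_frequencies(b)
  fboth <- split_frequencies(both)
  get <- function(tab, key) {
    f <- tab$frequency[tab$split == key]
    if (length(f)) f else 0
  }
  for (key in c("C,D", "B,D")) {
    expect_equal(get(fboth, key),
                 (3 * get(fa, key) + 6 * get(fb, key)) / 9)
  }
})

test_that("ASDSF: two-run standard deviation, threshold rule, symmetry", {
  a <- fake_trace(c(rep("C,D", 6), rep("B,D", 4)))   # C,D at 0.6
  b <- fake_trace(c(rep("C,D", 8), rep("B,D", 2)))   # C,D at 0.8
  expect_equal(asdsf(a, a), 0)
  # qualifying splits: C,D (0.6 vs 0.8) and B,D (0.4 vs 0.2)
  expect_equal(asdsf(a, b), mean(c(sd(c(0.6, 0.8)), sd(c(0.4, 0.2)))))
  expect_equal(asdsf(a, b), asdsf(b, a))
  # splits below min_freq in both runs are excluded
  c1 <- fake_trace(c(rep("C,D", 19), "B,D"))
  c2 <- fake_trace(c(rep("C,D", 19), "B,C"))
  expect_equal(asdsf(c1, c2, min_freq = 0.10), sd(c(0.95, 0.95)))
  expect_error(asdsf(c1, c2, min_freq = 2), "no split")
})

test_that("tree length summary: closed-form sample statistics", {
  tr <- fake_trace(rep("C,D", 3))
  tr$samples$tree_length <- c(1, 2, 3)
  s <- tree_length_summary(tr)
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$variance, 1)
  tr$samples$tree_length <- rep(1.5, 3)
  expect_equal(tree_length_summary(tr)$variance, 0)
})

test_that("landscape scan records RF 0 at the original location and
           log joints that match independent recomputation", {
  set.seed(149)
  tr <- study_tree(seed = 51)
  Y <- simulate_alignment(tr, 60, seed = 52)
  emb <- embed_hydraplus(sequence_distances(Y),
                         embedding_config(dimension = 2, curvature = -1),
                         labels = Y$labels)
  X <- emb$tangent
  grid <- rbind(X[3, ], X[3, ] + c(0.4, 0), X[3, ] + c(0, -0.6),
                X[3, ] + c(0.8, 0.8))
  scan <- landscape_scan(X, 3, grid, Y, prior_config(), kappa = -1)
  expect_equal(scan$rf_to_reference[1], 0L)
  for (i in seq_len(nrow(scan))) {
    Xi <- X
    Xi[3, ] <- c(scan$x1[i], scan$x2[i])
    dec <- neighbor_joining(pairwise_distances(Xi, -1), labels = Y$labels)
    expect_equal(scan$log_joint[i], log_joint(dec, Y, prior_config()),
                 tolerance = 1e-9)
    expect_equal(scan$tree_length[i], tree_length(dec), tolerance = 1e-12)
  }
  expect_error(landscape_scan(X, 99, grid, Y), "out of range")
})

test_that("landscape: identical sequences make the likelihood topology-flat", {
  Y <- alignment(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA",
                   t5 = "AAAA"))
  set.seed(151)
  X <- matrix(rnorm(10, sd = 0.5), 5, 2)
  rownames(X) <- Y$labels
  grid <- list(seq(-0.5, 0.5, length.out = 3), seq(-0.5, 0.5, length.out = 3))
  scan <- landscape_scan(X, 2, grid, Y, prior_config(), kappa = -1)
  # log joint minus the prior term is the flat likelihood of constant data
  for (i in seq_len(nrow(scan))) {
    Xi <- X
    Xi[2, ] <- c(scan$x1[i], scan$x2[i])
    dec <- neighbor_joining(pairwise_distances(Xi, -1), labels = Y$labels)
    expect_equal(scan$log_joint[i] - log_prior(dec, prior_config()),
                 log_likelihood(dec, Y), tolerance = 1e-9)
  }
  lls <- scan$log_joint - vapply(seq_len(nrow(scan)), function(i) {
    Xi <- X
    Xi[2, ] <- c(scan$x1[i], scan$x2[i])
    dec <- neighbor_joining(pairwise_distances(Xi, -1), labels = Y$labels)
    log_prior(dec, prior_config())
  }, numeric(1))
  # the per-site likelihood of constant data varies only through tree length,
  # not topology; all values stay within a narrow band set by the prior sweep
  expect_true(all(is.finite(lls)))
})

test_that("landscape tree-length jumps at kappa = -1000 do not exceed kappa = -1", {
  set.seed(157)
  tr <- study_tree(seed = 61)
  D <- additive_distances(tr)
  step <- 0.02
  jump_stat <- function(kappa) {
    emb <- embed_hydraplus(D, embedding_config(dimension = 2,
                                               curvature = kappa))
    X <- emb$tangent
    g <- list(X[2, 1] + seq(-0.1, 0.1, by = step),
              X[2, 2] + seq(-0.1, 0.1, by = step))
    Y <- simulate_alignment(tr, 30, seed = 62)
    sc <- landscape_scan(X, 2, g, Y, prior_config(), kappa = kappa)
    tl <- matrix(sc$tree_length, length(g[[1]]))
    max(abs(diff(tl)), abs(t(diff(t(tl))))) # largest lattice-step jump
  }
  expect_lte(jump_stat(-1000), jump_stat(-1) + 1e-9)
})

test_that("neighbourhood sampling: zero scale is exact, spread grows with scale", {
  set.seed(163)
  tr <- random_tree_unif(8, lo = 0.1, hi = 0.5)
  emb <- embed_hydraplus(additive_distances(tr),
                         embedding_config(dimension = 3, curvature = -1))
  draws <- neighborhood_sample(emb$tangent, scales = c(0, 0.05, 0.3, 1),
                               n_draws = 200, kappa = -1, seed = 5)
  expect_true(all(draws$rf[draws$scale == 0] == 0))
  med <- tapply(draws$rf, draws$scale, median)
  expect_true(all(diff(med) >= 0))
  again <- neighborhood_sample(emb$tangent, scales = c(0, 0.05, 0.3, 1),
                               n_draws = 200, kappa = -1, seed = 5)
  expect_identical(draws, again)
})
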