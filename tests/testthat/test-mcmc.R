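test_that("proposals: degenerate scale, determinism, covariance calibration", {
  X <- matrix(c(0.1, 0.2, -0.3, 0.4), 2, 2)
  st <- list(X = X, scale = matrix(0, 4, 4))
  expect_equal(propose(st)$X, X)
  S <- t(chol(matrix(c(1, 0.4, 0.4, 0.5), 2, 2)))
  st2 <- list(X = matrix(0, 2, 1), scale = S)
  set.seed(5)
  a <- propose(st2)
  set.seed(5)
  b <- propose(st2)
  expect_identical(a, b)
  set.seed(6)
  inc <- t(replicate(1e4, as.numeric(propose(st2)$X)))
  expect_equal(cov(inc), tcrossprod(S), tolerance = 0.05)
})

test_that("acceptance probability: tempered Metropolis ratio", {
  expect_equal(accept_probability(-10, -5), 1)
  expect_equal(accept_probability(-5, -5), 1)
  expect_equal(accept_probability(-5, -5 - log(2)), 0.5)
  expect_equal(accept_probability(-5, -5 - log(2), beta = 0.5), sqrt(0.5))
  expect_equal(accept_probability(-5, -Inf), 0)
  expect_equal(accept_probability(-5, NaN), 0)
})

test_that("RAM adaptation: fixed point at target, diminishing steps", {
  S <- diag(0.5, 3)
  z <- c(1, -2, 0.5)
  expect_equal(ram_adapt(S, z, 0.234, 10, target_rate = 0.234), S)
  S2 <- ram_adapt(S, z, 1, 10)
  expect_true(all(S2[upper.tri(S2)] == 0))
  expect_true(all(diag(S2) > 0))
  # covariance grows when accepting more than the target, shrinks otherwise
  expect_gt(sum(diag(tcrossprod(S2))), sum(diag(tcrossprod(S))))
  S3 <- ram_adapt(S, z, 0, 10)
  expect_lt(sum(diag(tcrossprod(S3))), sum(diag(tcrossprod(S))))
  # eta_i = min(1, dim * i^(-2/3)) vanishes: late updates are negligible
  Sl <- ram_adapt(S, z, 1, 1e9)
  expect_lt(max(abs(tcrossprod(Sl) - tcrossprod(S))), 1e-4)
})

test_that("RAM drives acceptance to the target rate on a Gaussian target", {
  set.seed(131)
  d <- 2
  x <- rep(0, d)
  S <- diag(5, d) # deliberately badly scaled start
  acc <- numeric(5e4)
  for (i in seq_along(acc)) {
    z <- rnorm(d)
    xc <- x + as.numeric(S %*% z)
    a <- min(1, exp(-0.5 * (sum(xc^2) - sum(x^2))))
    if (runif(1) < a) x <- xc
    S <- ram_adapt(S, z, a, i)
    acc[i] <- a
  }
  expect_equal(mean(acc[2.5e4:5e4]), 0.234, tolerance = 0.05)
})

test_that("swap moves exchange states with the tempered ratio", {
  mk <- function(lp, beta) list(X = matrix(lp, 1, 1), edge = NULL, len = NULL,
                                loglik = lp, lp = lp, beta = beta)
  # identical log joints: always accepted
  set.seed(137)
  st <- list(mk(-10, 1), mk(-10, 0.9))
  out <- swap_move(st, n_swaps = 20)
  expect_equal(out$accepted, 20L)
  # single chain: no-op
  one <- swap_move(st[1], n_swaps = 5)
  expect_equal(one$attempted, 0L)
  # a hot chain in a better state always swaps into the cold chain
  st2 <- list(mk(-100, 1), mk(-1, 0.5))
  out2 <- swap_move(st2, n_swaps = 1)
  expect_equal(out2$states[[1]]$lp, -1)
  expect_equal(out2$states[[1]]$beta, 1)
})

test_that("zero post-warm-up generations return the decoded start state", {
  set.seed(139)
  tr <- study_tree(seed = 11)
  Y <- simulate_alignment(tr, 100, seed = 12)
  cfg <- mcmc_config(generations = 0, warmup = 0, n_chains = 1,
                     start = "given_tree", seed = 3)
  trace <- run_mcmc(Y, cfg, start_tree = tr)
  expect_equal(nrow(trace$samples), 1)
  expect_equal(trace$samples$generation, 0L)
  dec <- trace_trees(trace)[[1]]
  # the start state decodes the embedded start tree (additive distances)
  expect_equal(rf_distance(dec, tr), 0)
})

test_that("traces are reproducible and cache-coherent", {
  tr <- study_tree(seed = 21)
  Y <- simulate_alignment(tr, 120, seed = 22)
  cfg <- mcmc_config(generations = 1500, warmup = 500, n_chains = 2,
                     n_samples = 50, seed = 7, swap_interval = 200)
  t1 <- run_mcmc(Y, cfg)
  t2 <- run_mcmc(Y, cfg)
  expect_identical(t1$samples, t2$samples)
  # cached log joint equals recomputation at every retained sample
  trees <- trace_trees(t1)
  for (k in seq_along(trees)) {
    expect_equal(log_joint(trees[[k]], Y, cfg$prior),
                 t1$samples$log_joint[k], tolerance = 1e-9)
  }
  expect_equal(nrow(t1$samples), 50)
})

test_that("Euclidean mode runs end-to-end and produces a valid trace", {
  tr <- study_tree(seed = 31)
  Y <- simulate_alignment(tr, 100, seed = 32)
  cfg <- mcmc_config(generations = 800, warmup = 300, n_chains = 1,
                     curvature = 0, n_samples = 40, seed = 9)
  trace <- run_mcmc(Y, cfg)
  expect_equal(nrow(trace$samples), 40)
  expect_true(all(is.finite(trace$samples$log_joint)))
  expect_true(all(trace$samples$tree_length >= 0))
})

test_that("embedding-normal prior mode runs and scores states by coordinates", {
  tr <- study_tree(seed = 41)
  Y <- simulate_alignment(tr, 100, seed = 42)
  cfg <- mcmc_config(generations = 600, warmup = 200, n_chains = 1,
                     n_samples = 30, seed = 13,
                     prior = prior_config(mode = "embedding_normal"))
  trace <- run_mcmc(Y, cfg)
  expect_equal(nrow(trace$samples), 30)
  k <- nrow(trace$samples)
  trees <- trace_trees(trace)
  lp <- log_likelihood(trees[[k]], Y) +
    sum(dnorm(as.numeric(trace$states[[k]]), log = TRUE))
  expect_equal(trace$samples$log_joint[k], lp, tolerance = 1e-9)
})
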