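# shared small dataset for chain tests
chain_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(314)
      K <- 6
      G <- as.matrix(expand.grid(x = 1:3, y = 1:2))
      data <- simulate_mvn(G, a0 = 1, a1 = 0.6, a2 = 1, eta = rep(0.05, K),
                           Sbar = rep(10, K), L = 1500)
      cache <<- list(G = G, K = K, data = data)
    }
    cache
  }
})

test_that("trace bookkeeping: sample count, reproducibility, seed control", {
  fx <- chain_fixture()
  cfg <- model_config(variant = 2, obs_locations = fx$G, metric = "plane",
                      n_iter = 5000, thin = 50)
  tr1 <- run_mcmc(fx$data, cfg, seed = 5)
  tr2 <- run_mcmc(fx$data, cfg, seed = 5)
  tr3 <- run_mcmc(fx$data, cfg, seed = 6)
  expect_equal(nrow(tr1$samples), 100)          # n_iter / thin
  expect_identical(tr1$samples, tr2$samples)    # same seed, same chain
  expect_false(identical(tr1$samples, tr3$samples))
})

test_that("recorded log posterior is recomputable from the stored state", {
  fx <- chain_fixture()
  cfg <- model_config(variant = 4, obs_locations = fx$G, metric = "plane",
                      n_iter = 8000, thin = 200)
  tr <- run_mcmc(fx$data, cfg, seed = 11)
  for (i in seq_len(nrow(tr$samples))) {
    st <- trace_state(tr, i)
    expect_equal(tr$log_post[i],
                 mapmix:::state_loglik(st, fx$data, cfg) + log_prior(st, cfg),
                 tolerance = 1e-6)
  }
})

test_that("spherical chains satisfy the same posterior recomputation", {
  set.seed(21)
  K <- 5
  G <- cbind(runif(K, -30, 30), runif(K, -20, 20))
  data <- simulate_mvn(G, 1, 2, 1, rep(0.05, K), rep(10, K), L = 800,
                       metric = "sphere")
  cfg <- model_config(variant = 4, obs_locations = G, metric = "sphere",
                      n_iter = 6000, thin = 300)
  tr <- run_mcmc(data, cfg, seed = 2)
  for (i in seq_len(nrow(tr$samples))) {
    st <- trace_state(tr, i)
    expect_equal(tr$log_post[i],
                 mapmix:::state_loglik(st, data, cfg) + log_prior(st, cfg),
                 tolerance = 1e-6)
  }
  # longitude/latitude stay in range
  lon <- tr$samples[, grep("^G.*_x$", colnames(tr$samples))]
  lat <- tr$samples[, grep("^G.*_y$", colnames(tr$samples))]
  expect_true(all(lon >= -180 & lon <= 180))
  expect_true(all(lat >= -90 & lat <= 90))
})

test_that("parameters outside the variant's free set never move", {
  fx <- chain_fixture()
  cfg <- model_config(variant = 2, obs_locations = fx$G, metric = "plane",
                      n_iter = 5000, thin = 50)
  tr <- run_mcmc(fx$data, cfg, seed = 9)
  K <- fx$K
  wcols <- tr$samples[, 3 + K + 1:K, drop = FALSE]
  expect_true(all(wcols == 0))
  gs <- tr$samples[, 3 + 4 * K + 1:(2 * K), drop = FALSE]
  expect_true(all(apply(gs, 2, function(x) length(unique(x))) == 1))

  cfg3 <- model_config(variant = 3, obs_locations = fx$G, metric = "plane",
                       n_iter = 5000, thin = 50)
  tr3 <- run_mcmc(fx$data, cfg3, seed = 9)
  gfix <- tr3$samples[, 3 + 2 * K + 1:(2 * K), drop = FALSE]
  expect_true(all(apply(gfix, 2, function(x) length(unique(x))) == 1))
  expect_true(any(tr3$samples[, 3 + K + 1:K] > 0))  # w does move
})

test_that("single-parameter chain matches the grid-quadrature posterior", {
  # all blocks but a1 fixed at the truth; the 1-D marginal of the sampler
  # must match the exact normalized posterior on a fine grid
  set.seed(42)
  K <- 5
  G <- cbind(runif(K, 0, 3), runif(K, 0, 3))
  truth <- list(a0 = 1, a1 = 0.8, a2 = 1, eta = rep(0.1, K))
  data <- simulate_mvn(G, truth$a0, truth$a1, truth$a2, truth$eta,
                       rep(10, K), L = 400)
  cfg <- model_config(variant = 1, obs_locations = G, metric = "plane",
                      n_iter = 1e5, thin = 10, free = "a1")
  init <- list(a0 = 1, a1 = 0.8, a2 = 1, eta = rep(0.1, K), w = rep(0, K),
               G = G, Gstar = G)
  tr <- run_mcmc(data, cfg, init = init, seed = 77)
  n <- nrow(tr$samples)
  draws <- tr$samples[(n / 2 + 1):n, "alpha1"]

  grid <- seq(max(1e-4, min(draws) - 0.3), max(draws) + 0.3, length.out = 400)
  logpost <- vapply(grid, function(a1) {
    st <- modifyList(init, list(a1 = a1))
    mapmix:::state_loglik(st, data, cfg) + dexp(a1, 1, log = TRUE)
  }, numeric(1))
  dens <- exp(logpost - max(logpost))
  cdf <- cumsum(dens) / sum(dens)
  ks <- suppressWarnings(stats::ks.test(draws, function(q) {
    approx(grid, cdf, xout = q, rule = 2)$y
  })$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("adaptation drives acceptance toward 0.44", {
  fx <- chain_fixture()
  cfg <- model_config(variant = 1, obs_locations = fx$G, metric = "plane",
                      n_iter = 2e5, thin = 1000)
  tr <- run_mcmc(fx$data, cfg, seed = 13)
  rates <- acceptance_rates(tr)[mapmix:::free_block_ids(cfg) + 1L]
  expect_true(all(abs(rates - 0.44) < 0.05))
})

test_that("protocol selects the best short run and returns the long trace", {
  fx <- chain_fixture()
  cfg <- model_config(variant = 4, obs_locations = fx$G, metric = "plane",
                      n_iter = 1000, thin = 10)
  tr <- run_protocol(fx$data, cfg, n_short = 3, short_len = 3000,
                     long_len = 4000, seed = 99)
  expect_equal(nrow(tr$samples), 400)  # long_len / thin
  expect_equal(tr$protocol$best_short,
               which.max(tr$protocol$short_final_log_post))
  expect_length(tr$protocol$short_final_log_post, 3)
  # degenerate protocol: a single short run still works
  tr1 <- run_protocol(fx$data, cfg, n_short = 1, short_len = 2000,
                      long_len = 2000, seed = 1)
  expect_equal(tr1$protocol$best_short, 1)
})

test_that("variant-4 on admixture-free data keeps admixture small", {
  set.seed(55)
  K <- 8
  G <- as.matrix(expand.grid(x = 1:4, y = 1:2))
  data <- simulate_mvn(G, 1, 0.5, 1, rep(0.05, K), rep(10, K), L = 3000)
  cfg <- model_config(variant = 4, obs_locations = G, metric = "plane",
                      n_iter = 3e5, thin = 500)
  tr <- run_mcmc(data, cfg, seed = 3)
  n <- nrow(tr$samples)
  wbar <- colMeans(tr$samples[(n / 2 + 1):n, 3 + K + 1:K, drop = FALSE])
  expect_true(all(wbar < 0.05))
})

test_that("credible intervals for a1 cover the truth across replicates", {
  # calibration: exact-model data, fixed locations, free decay + nuggets
  K <- 6
  G <- as.matrix(expand.grid(x = 1:3, y = 1:2))
  hits <- 0L
  for (rep in 1:20) {
    set.seed(1000 + rep)
    data <- simulate_mvn(G, a0 = 1, a1 = 1, a2 = 1, eta = rep(0.1, K),
                         Sbar = rep(10, K), L = 1000)
    cfg <- model_config(variant = 1, obs_locations = G, metric = "plane",
                        n_iter = 3e5, thin = 500)
    tr <- run_mcmc(data, cfg, seed = 2000 + rep)
    n <- nrow(tr$samples)
    ci <- quantile(tr$samples[(n / 2 + 1):n, "alpha1"], c(0.025, 0.975))
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
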