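test_that("great-circle distances match closed forms and geosphere", {
  a <- rbind(c(0, 0), c(90, 0), c(180, 0), c(0, 90))
  D <- distance_matrix(a, metric = "sphere")
  expect_equal(diag(D), rep(0, 4))
  expect_equal(D[1, 2], pi / 2)
  expect_equal(D[1, 3], pi)          # antipodal
  expect_equal(D[1, 4], pi / 2)
  skip_if_not_installed("geosphere")
  set.seed(2)
  P <- cbind(runif(6, -180, 180), runif(6, -85, 85))
  Dref <- geosphere::distm(P, fun = geosphere::distHaversine) / 6378137
  expect_equal(distance_matrix(P, metric = "sphere"), Dref, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("powered-exponential decay evaluates and decreases", {
  expect_equal(spatial_cov(0, 2, 1, 1), 0.5)          # sill = 1/a0
  expect_equal(spatial_cov(log(2), 1, 1, 1), 0.5)
  d <- seq(0, 5, by = 0.25)
  v <- spatial_cov(d, 1.3, 0.8, 1.4)
  expect_true(all(diff(v) < 0))
  expect_error(spatial_cov(1, 1, 1, 2.5), "a2")
})

test_that("model covariance assembles decay, nugget and sampling noise", {
  ins <- rand_instance(4, 21)
  Om <- model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                  metric = "plane")
  D <- distance_matrix(ins$G, metric = "plane")
  expect_equal(diag(Om), 1 / ins$a0 + ins$eta + 1 / ins$Sbar,
               ignore_attr = TRUE)
  expect_equal(Om[1, 2], spatial_cov(D[1, 2], ins$a0, ins$a1, ins$a2))
  # coincident populations, no nugget, huge samples: singular constant block
  Om2 <- model_cov(rbind(c(0, 0), c(0, 0)), 2, 1, 1, c(0, 0), c(1e12, 1e12),
                   metric = "plane")
  expect_equal(Om2, matrix(0.5, 2, 2), tolerance = 1e-9)
})

test_that("admixed covariance matches the four-term sum and its degeneracies", {
  ins <- rand_instance(3, 31)
  Gs <- ins$G + 1.5
  w0 <- rep(0, 3)
  expect_equal(
    admixed_cov(ins$G, Gs, w0, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                metric = "plane"),
    model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
              metric = "plane"))
  # w = 0.5 with sources at the populations' own locations changes nothing
  expect_equal(
    admixed_cov(ins$G, ins$G, rep(0.5, 3), ins$a0, ins$a1, ins$a2, ins$eta,
                ins$Sbar, metric = "plane"),
    model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
              metric = "plane"))

  # K = 2 brute-force term-by-term evaluation
  G <- rbind(c(0, 0), c(2, 0)); Gs <- rbind(c(5, 1), c(-3, 2))
  w <- c(0.4, 0); a0 <- 1.2; a1 <- 0.7; a2 <- 1.1
  eta <- c(0.1, 0.2); Sbar <- c(10, 8)
  f <- function(p, q) (1 / a0) * exp(-(a1 * sqrt(sum((p - q)^2)))^a2)
  expected <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    gi <- G[i, ]; gj <- G[j, ]; si <- Gs[i, ]; sj <- Gs[j, ]
    expected[i, j] <- (1 - w[i]) * (1 - w[j]) * f(gi, gj) +
      w[i] * (1 - w[j]) * f(si, gj) +
      w[j] * (1 - w[i]) * f(gi, sj) +
      w[i] * w[j] * f(si, sj)
  }
  expected <- expected + diag(eta + 1 / Sbar)
  got <- admixed_cov(G, Gs, w, a0, a1, a2, eta, Sbar, metric = "plane")
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("projected Wishart log-likelihood equals an independent oracle", {
  for (seed in 1:4) {
    K <- sample(3:5, 1)
    ins <- rand_instance(K, 100 + seed)
    Om_star <- model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                         metric = "plane")
    data <- simulate_mvn(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                         L = 200)
    L <- data$L_eff; Psi <- data$Psi
    got <- wishart_loglik(data$omega_hat, Om_star, Psi, L)
    ref <- oracle_wishart_logpdf(L * t(Psi) %*% data$omega_hat %*% Psi,
                                 t(Psi) %*% Om_star %*% Psi, L)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  expect_error(wishart_loglik(diag(3), diag(3), diag(3)[, 1:2], 1),
               "insufficient loci")
})

test_that("likelihood is invariant to rigid motions and projection basis", {
  ins <- rand_instance(4, 55)
  data <- simulate_mvn(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                       L = 300)
  base <- wishart_loglik(
    data$omega_hat,
    model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar, "plane"),
    data$Psi, data$L_eff)

  set.seed(99)
  for (rep in 1:5) {
    th <- runif(1, 0, 2 * pi)
    Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    G2 <- ins$G %*% Rm + matrix(rnorm(2, sd = 3), 4, 2, byrow = TRUE)
    v <- wishart_loglik(
      data$omega_hat,
      model_cov(G2, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar, "plane"),
      data$Psi, data$L_eff)
    expect_equal(v, base, tolerance = 1e-10)
  }

  # any orthonormal basis of col(T) gives the same value
  for (rep in 1:5) {
    R3 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random 3x3 orthogonal
    Psi2 <- data$Psi %*% R3
    v <- wishart_loglik(
      data$omega_hat,
      model_cov(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar, "plane"),
      Psi2, data$L_eff)
    expect_equal(v, base, tolerance = 1e-8)
  }
})

test_that("Wishart and per-locus Gaussian log-likelihoods differ by a constant", {
  ins <- rand_instance(4, 77)
  data <- simulate_mvn(ins$G, ins$a0, ins$a1, ins$a2, ins$eta, ins$Sbar,
                       L = 60)
  Y <- crossprod(data$Psi, data$Xhat)   # projected per-locus data, (K-1) x L
  diffs <- sapply(1:4, function(s) {
    p2 <- rand_instance(4, 200 + s)
    Om <- model_cov(ins$G, p2$a0, p2$a1, p2$a2, p2$eta, ins$Sbar, "plane")
    V <- crossprod(data$Psi, Om %*% data$Psi)
    gauss <- sum(apply(Y, 2, oracle_mvn_logpdf, V = V))
    wish <- wishart_loglik(data$omega_hat, Om, data$Psi, data$L_eff)
    gauss - wish
  })
  expect_lt(diff(range(diffs)), 1e-6)
})

test_that("non-positive-definite projected covariance yields -Inf, no error", {
  # Gaussian-shaped decay (a2 = 2) on widely spaced sphere points is not a
  # valid covariance: the matrix genuinely loses positive definiteness
  G <- cbind(seq(0, 160, by = 40), rep(0, 5))
  Om <- model_cov(G, 1, 4, 2, rep(0, 5), rep(1e9, 5), metric = "sphere")
  Om[1, 5] <- Om[5, 1] <- 5     # long-distance excess breaks PD
  expect_lt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), 0)
  set.seed(8)
  data <- simulate_mvn(cbind(rnorm(5), rnorm(5)), 1, 1, 1,
                       rep(0.1, 5), rep(10, 5), L = 50)
  V <- crossprod(data$Psi, Om %*% data$Psi)
  expect_lt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(wishart_loglik(data$omega_hat, Om, data$Psi, data$L_eff),
                   -Inf)
})
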