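# shared fixtures and independent oracles

# independently coded Wishart log density (textbook formula: explicit
# multivariate gamma, determinant and solve(); no Cholesky shortcuts shared
# with the implementation)
oracle_wishart_logpdf <- function(X, V, n) {
  p <- nrow(X)
  lg <- p * (p - 1) / 4 * log(pi)
  for (j in 1:p) lg <- lg + lgamma(n / 2 + (1 - j) / 2)
  (n - p - 1) / 2 * log(det(X)) -
    sum(diag(solve(V) %*% X)) / 2 -
    n * p / 2 * log(2) - n / 2 * log(det(V)) - lg
}

# multivariate normal log density at x (mean zero), textbook form
oracle_mvn_logpdf <- function(x, V) {
  p <- length(x)
  -p / 2 * log(2 * pi) - 0.5 * log(det(V)) -
    0.5 * as.numeric(t(x) %*% solve(V) %*% x)
}

# random small planar configuration and PD model covariance
rand_instance <- function(K, seed) {
  set.seed(seed)
  list(G = cbind(runif(K, 0, 4), runif(K, 0, 4)),
       a0 = runif(1, 0.5, 2), a1 = runif(1, 0.3, 1.5),
       a2 = runif(1, 0.5, 1.5), eta = runif(K, 0, 0.3),
       Sbar = sample(5:20, K, replace = TRUE))
}

# tiny allele-count fixture
toy_counts <- function() {
  C <- rbind(c(1, 0, 3, 2), c(2, 0, 1, 4), c(3, 4, 2, 0))
  S <- matrix(4, 3, 4)
  allele_counts(C, S)
}

# small, fast lattice scenario for coalescent smoke tests
small_scenario <- function(..., n_loci = 300) {
  build_scenario(n_row = 7L, n_col = 7L, n_loci = n_loci, ...)
}

has_msprime <- function() {
  py <- tryCatch(mapmix:::python_binary(), error = function(e) NULL)
  if (is.null(py)) return(FALSE)
  code <- suppressWarnings(
    system2(py, c("-c", shQuote("import msprime")), stdout = FALSE,
            stderr = FALSE))
  identical(code, 0L)
}
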