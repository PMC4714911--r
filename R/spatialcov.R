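#' Pairwise distance matrix (unit sphere or plane)
#'
#' Great-circle distances on the unit sphere (coordinates in degrees of
#' longitude and latitude; distances in radians) or Euclidean distances in an
#' abstract plane. All model distances in the package are in these units.
#'
#' @param a n x 2 coordinate matrix (lon, lat degrees, or x, y).
#' @param b optional m x 2 matrix; defaults to `a`.
#' @param metric `"sphere"` (default) or `"plane"`.
#' @return n x m matrix of pairwise distances.
#' @export
distance_matrix <- function(a, b = NULL, metric = c("sphere", "plane")) {
  metric <- match.arg(metric)
  a <- as.matrix(a)
  b <- if (is.null(b)) a else as.matrix(b)
  if (ncol(a) != 2L || ncol(b) != 2L) stop("coordinates must be n x 2")
  if (metric == "plane") {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    return(sqrt(dx^2 + dy^2))
  }
  gc_dist_deg(a, b)
}

# haversine great-circle distance on the unit sphere, degrees in, radians out
gc_dist_deg <- function(a, b) {
  lam1 <- a[, 1] * pi / 180; phi1 <- a[, 2] * pi / 180
  lam2 <- b[, 1] * pi / 180; phi2 <- b[, 2] * pi / 180
  dphi <- outer(phi1, phi2, "-")
  dlam <- outer(lam1, lam2, "-")
  h <- sin(dphi / 2)^2 +
    outer(cos(phi1), cos(phi2)) * sin(dlam / 2)^2
  h[h > 1] <- 1; h[h < 0] <- 0
  2 * asin(sqrt(h))
}

#' Powered-exponential spatial covariance
#'
#' `F(D) = (1/a0) * exp(-(a1 * D)^a2)`, the decay curve relating geogenetic
#' distance to allele-frequency covariance. `1/a0` is the sill (covariance at
#' distance 0), `a1` the decay rate per unit distance, and `a2 in (0.1, 2]`
#' the shape of the decay.
#'
#' @param D nonnegative distance matrix (or vector).
#' @param a0,a1 positive reals.
#' @param a2 real in (0.1, 2].
#' @return matrix (or vector) of covariances, same shape as `D`.
#' @export
spatial_cov <- function(D, a0, a1, a2) {
  check_cov_params(a0, a1, a2)
  if (any(D < 0)) stop("distances must be nonnegative")
  (1 / a0) * exp(-(a1 * D)^a2)
}

check_cov_params <- function(a0, a1, a2) {
  if (!is.finite(a0) || a0 <= 0) stop("a0 must be positive")
  if (!is.finite(a1) || a1 <= 0) stop("a1 must be positive")
  if (!is.finite(a2) || a2 <= 0.1 || a2 > 2) stop("a2 must lie in (0.1, 2]")
  invisible(TRUE)
}

#' Parametric covariance of standardized frequencies (no admixture)
#'
#' `Omega[i,j] = F(D_ij) + d_ij * (1/Sbar_i + eta_i)`: the spatial decay
#' curve off the diagonal, plus the sampling-noise term and the nugget
#' `eta_i` (population-specific variance unexplained by the spatial model)
#' on the diagonal.
#'
#' @param G K x 2 location matrix.
#' @param a0,a1,a2 decay parameters, see [spatial_cov()].
#' @param eta nonnegative nugget vector of length K.
#' @param Sbar mean sample sizes, length K.
#' @param metric `"sphere"` or `"plane"`.
#' @return K x K covariance matrix.
#' @export
model_cov <- function(G, a0, a1, a2, eta, Sbar, metric = c("sphere", "plane")) {
  metric <- match.arg(metric)
  G <- as.matrix(G)
  K <- nrow(G)
  if (length(eta) != K || length(Sbar) != K) {
    stop("G, eta and Sbar must all describe the same K populations")
  }
  if (any(eta < 0)) stop("nuggets must be nonnegative")
  D <- distance_matrix(G, metric = metric)
  spatial_cov(D, a0, a1, a2) + diag(1 / Sbar + eta, K)
}

#' Parametric covariance with admixture
#'
#' Each population k draws a fraction `w_k` of its alleles from a source
#' location `Gstar_k` and `1 - w_k` from its own location `G_k`, so the
#' covariance between populations i and j is the four-term mixture of the
#' spatial covariances among the 2K locations:
#' `(1-w_i)(1-w_j) F(D_ij) + w_i(1-w_j) F(D_i*j) + w_j(1-w_i) F(D_ij*) +
#'  w_i w_j F(D_i*j*)`, plus the diagonal nugget and sampling terms.
#' With all `w = 0` this reduces exactly to [model_cov()].
#'
#' @param G,Gstar K x 2 matrices of population and admixture-source locations.
#' @param w admixture proportions in `[0, 0.5]`.
#' @inheritParams model_cov
#' @return K x K covariance matrix.
#' @export
admixed_cov <- function(G, Gstar, w, a0, a1, a2, eta, Sbar,
                        metric = c("sphere", "plane")) {
  metric <- match.arg(metric)
  G <- as.matrix(G); Gstar <- as.matrix(Gstar)
  K <- nrow(G)
  if (nrow(Gstar) != K || length(w) != K || length(eta) != K ||
      length(Sbar) != K) {
    stop("G, Gstar, w, eta, Sbar must all describe the same K populations")
  }
  if (any(w < 0 | w > 0.5)) stop("admixture proportions must lie in [0, 0.5]")
  if (any(eta < 0)) stop("nuggets must be nonnegative")
  D <- distance_matrix(rbind(G, Gstar), metric = metric)
  FF <- spatial_cov(D, a0, a1, a2)
  gi <- seq_len(K); si <- K + gi
  Fgg <- FF[gi, gi]; Fsg <- FF[si, gi]; Fss <- FF[si, si]
  u <- 1 - w
  outer(u, u) * Fgg + outer(w, u) * Fsg + outer(u, w) * t(Fsg) +
    outer(w, w) * Fss + diag(eta + 1 / Sbar, K)
}

# log of the multivariate gamma function, dimension p
lmvgamma <- function(p, a) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Projected Wishart log-likelihood of the sample covariance
#'
#' The standardized sample covariance has rank K-1, so the likelihood is
#' evaluated on the full-rank (K-1)-dimensional projection: the log density
#' of `L * t(Psi) %*% omega_hat %*% Psi` under a Wishart with `L` degrees of
#' freedom and scale `t(Psi) %*% omega_star %*% Psi`, including the full
#' normalizing constant. If the projected model covariance is not positive
#' definite the function returns `-Inf` (the sampler treats this as a
#' rejection; no jitter or other silent regularization is applied).
#'
#' @param omega_hat K x K sample covariance ([standardize_freqs()]).
#' @param omega_star K x K model covariance ([model_cov()]/[admixed_cov()]).
#' @param Psi K x (K-1) orthonormal projection ([projection_matrix()]).
#' @param L number of loci (degrees of freedom); must be at least K-1.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
wishart_loglik <- function(omega_hat, omega_star, Psi, L) {
  p <- ncol(Psi)
  if (L < p) stop("insufficient loci for full-rank projected covariance")
  A <- L * crossprod(Psi, omega_hat %*% Psi)
  V <- crossprod(Psi, omega_star %*% Psi)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) stop("projected sample covariance is not positive definite")
  ldA <- 2 * sum(log(diag(cA)))
  ldV <- 2 * sum(log(diag(cV)))
  tr <- sum(backsolve(cV, backsolve(cV, A, transpose = TRUE))[cbind(1:p, 1:p)])
  (L - p - 1) / 2 * ldA - tr / 2 - L * p / 2 * log(2) - L / 2 * ldV -
    lmvgamma(p, L / 2)
}
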