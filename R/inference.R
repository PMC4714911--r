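#' Model configuration for geogenetic-map inference
#'
#' Assembles the model variant, priors and chain settings. The four variants
#' differ in which parameter blocks are free:
#' \describe{
#'   \item{1}{fixed locations, no admixture: `a0, a1, a2, eta`}
#'   \item{2}{inferred locations, no admixture: adds `G`}
#'   \item{3}{fixed locations, inferred admixture: adds `Gstar, w` to variant 1}
#'   \item{4}{inferred locations and admixture: all blocks free}
#' }
#'
#' Priors: `a0 ~ Exp(1/100)`, `a1 ~ Exp(1)`, `a2 ~ U(0.1, 2)`,
#' `eta_k ~ Exp(1)`, `2 w_k ~ Beta(1, 100)` (capped at `w = 0.5`),
#' `G_k ~ N(center_k, sd = Dbar/2)` and `Gstar_k ~ N(centroid, sd = 2 Dbar)`
#' isotropic in model distance, where `Dbar` is the mean pairwise distance
#' between the prior location centers.
#'
#' @param variant integer 1-4.
#' @param obs_locations K x 2 matrix of observed coordinates, or `NULL` for a
#'   fully unanchored analysis (prior centers are then drawn uniformly on the
#'   unit square).
#' @param K number of populations (required when `obs_locations` is `NULL`).
#' @param metric `"plane"` or `"sphere"`.
#' @param location_prior `"observed"` centers each population's location
#'   prior on its observed coordinates; `"random"` replaces the centers with
#'   uniform draws from the bounding box of the observed coordinates (drawn
#'   once, using the current RNG state, when the config is built).
#' @param n_iter,thin chain length and thinning interval.
#' @param rate_a0,rate_a1,rate_eta exponential prior rates.
#' @param a2_bounds support of the uniform prior on `a2`.
#' @param w_beta shape parameters of the Beta prior on `2w`.
#' @param sigma_G,sigma_Gstar location prior standard deviations; default
#'   `Dbar/2` and `2 Dbar`.
#' @param zeta_cap clamp for the log proposal scales (proposal variance is
#'   then at most `exp(2 * zeta_cap)`).
#' @param adapt_window proposals per adaptation window (default 50).
#' @param free optional character vector overriding the variant's free block
#'   types (subset of `"a0","a1","a2","eta","w","G","Gstar"`); intended for
#'   calibration experiments with all other blocks held fixed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = 4L, obs_locations = NULL, K = NULL,
                         metric = c("plane", "sphere"),
                         location_prior = c("observed", "random"),
                         n_iter = 1e5, thin = 100,
                         rate_a0 = 1 / 100, rate_a1 = 1, rate_eta = 1,
                         a2_bounds = c(0.1, 2), w_beta = c(1, 100),
                         sigma_G = NULL, sigma_Gstar = NULL,
                         zeta_cap = 10, adapt_window = 50L, free = NULL) {
  metric <- match.arg(metric)
  location_prior <- match.arg(location_prior)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4")
  if (is.null(obs_locations)) {
    if (is.null(K)) stop("supply obs_locations or K")
    obs_locations <- NULL
  } else {
    obs_locations <- as.matrix(obs_locations)
    K <- nrow(obs_locations)
  }

  if (is.null(obs_locations)) {
    centers <- cbind(runif(K), runif(K))
    box <- rbind(c(0, 1), c(0, 1))
  } else {
    box <- rbind(range(obs_locations[, 1]), range(obs_locations[, 2]))
    centers <- if (location_prior == "random") {
      cbind(runif(K, box[1, 1], box[1, 2]), runif(K, box[2, 1], box[2, 2]))
    } else obs_locations
  }
  D <- distance_matrix(centers, metric = metric)
  Dbar <- mean(D[upper.tri(D)])
  if (!is.finite(Dbar) || Dbar <= 0) Dbar <- 1
  if (is.null(sigma_G)) sigma_G <- Dbar / 2
  if (is.null(sigma_Gstar)) sigma_Gstar <- 2 * Dbar
  centroid <- colMeans(centers)

  types <- if (!is.null(free)) {
    stopifnot(all(free %in% c("a0", "a1", "a2", "eta", "w", "G", "Gstar")))
    free
  } else {
    switch(variant,
           c("a0", "a1", "a2", "eta"),
           c("a0", "a1", "a2", "eta", "G"),
           c("a0", "a1", "a2", "eta", "w", "Gstar"),
           c("a0", "a1", "a2", "eta", "w", "G", "Gstar"))
  }

  structure(
    list(variant = variant, K = K, metric = metric,
         location_prior = location_prior,
         obs_locations = obs_locations, prior_G_mean = centers,
         prior_Gstar_mean = matrix(centroid, K, 2, byrow = TRUE),
         coord_box = box, Dbar = Dbar,
         sigma_G = sigma_G, sigma_Gstar = sigma_Gstar,
         rate_a0 = rate_a0, rate_a1 = rate_a1, rate_eta = rate_eta,
         a2_bounds = a2_bounds, w_beta = w_beta,
         n_iter = n_iter, thin = thin,
         zeta_cap = zeta_cap, adapt_window = as.integer(adapt_window),
         free_types = types),
    class = "model_config")
}

# block bookkeeping: 0-based ids matching the C++ engine
# 0 = a0, 1 = a1, 2 = a2, 3..K+2 = eta_k, K+3..2K+2 = w_k,
# 2K+3..3K+2 = G_k, 3K+3..4K+2 = Gstar_k
block_names <- function(cfg) {
  K <- cfg$K
  c("a0", "a1", "a2", paste0("eta_", 1:K), paste0("w_", 1:K),
    paste0("G_", 1:K), paste0("Gstar_", 1:K))
}

free_block_ids <- function(cfg) {
  K <- cfg$K
  ids <- integer(0)
  t <- cfg$free_types
  if ("a0" %in% t) ids <- c(ids, 0L)
  if ("a1" %in% t) ids <- c(ids, 1L)
  if ("a2" %in% t) ids <- c(ids, 2L)
  if ("eta" %in% t) ids <- c(ids, 3L + 0:(K - 1L))
  if ("w" %in% t) ids <- c(ids, 3L + K + 0:(K - 1L))
  if ("G" %in% t) ids <- c(ids, 3L + 2L * K + 0:(K - 1L))
  if ("Gstar" %in% t) ids <- c(ids, 3L + 3L * K + 0:(K - 1L))
  ids
}

loc_prior_logdens <- function(loc, mu, sigma, metric) {
  d <- unname(distance_matrix(rbind(loc), rbind(mu), metric = metric)[1, 1])
  -d^2 / (2 * sigma^2) - log(2 * pi * sigma^2)
}

#' Log prior density of a parameter state
#'
#' Sums the log prior densities of the blocks that are free under the
#' configuration's model variant (fixed blocks contribute nothing); returns
#' `-Inf` outside any prior's support.
#'
#' @param state a list with elements `a0, a1, a2, eta, w, G, Gstar` (see
#'   [init_state()]).
#' @param cfg a [model_config()].
#' @return scalar log prior density.
#' @export
log_prior <- function(state, cfg) {
  t <- cfg$free_types
  lp <- 0
  if ("a0" %in% t) {
    if (state$a0 <= 0) return(-Inf)
    lp <- lp + dexp(state$a0, cfg$rate_a0, log = TRUE)
  }
  if ("a1" %in% t) {
    if (state$a1 <= 0) return(-Inf)
    lp <- lp + dexp(state$a1, cfg$rate_a1, log = TRUE)
  }
  if ("a2" %in% t) {
    if (state$a2 <= cfg$a2_bounds[1] || state$a2 > cfg$a2_bounds[2]) return(-Inf)
    lp <- lp - log(cfg$a2_bounds[2] - cfg$a2_bounds[1])
  }
  if ("eta" %in% t) {
    if (any(state$eta < 0)) return(-Inf)
    lp <- lp + sum(dexp(state$eta, cfg$rate_eta, log = TRUE))
  }
  if ("w" %in% t) {
    if (any(state$w < 0 | state$w > 0.5)) return(-Inf)
    lp <- lp + sum(log(2) +
                     dbeta(2 * state$w, cfg$w_beta[1], cfg$w_beta[2], log = TRUE))
  }
  if ("G" %in% t) {
    for (k in seq_len(cfg$K)) {
      lp <- lp + loc_prior_logdens(state$G[k, ], cfg$prior_G_mean[k, ],
                                   cfg$sigma_G, cfg$metric)
    }
  }
  if ("Gstar" %in% t) {
    for (k in seq_len(cfg$K)) {
      lp <- lp + loc_prior_logdens(state$Gstar[k, ], cfg$prior_Gstar_mean[k, ],
                                   cfg$sigma_Gstar, cfg$metric)
    }
  }
  lp
}

#' Symmetric random-walk proposal for a scalar parameter
#'
#' Adds a zero-mean normal perturbation with standard deviation `exp(zeta)`.
#' Proposals outside a prior's support are handled by rejection (the prior
#' evaluates to `-Inf`), not by reflection or truncation.
#'
#' @param value current value.
#' @param zeta log of the proposal standard deviation.
#' @return proposed value.
#' @export
propose_scalar <- function(value, zeta) {
  value + exp(zeta) * rnorm(1)
}

#' Symmetric location proposal
#'
#' On the sphere, draws an arc distance `|N(0, exp(zeta)^2)|` and a uniform
#' bearing, and returns the great-circle destination point (standard
#' destination formulas; longitude wrapped to (-180, 180]). In the plane,
#' falls back to an isotropic Gaussian jitter of both coordinates.
#'
#' @param loc length-2 coordinate (lon, lat degrees, or x/y).
#' @param zeta log proposal scale.
#' @param metric `"sphere"` or `"plane"`.
#' @return proposed coordinate, length 2.
#' @export
propose_location <- function(loc, zeta, metric = c("sphere", "plane")) {
  metric <- match.arg(metric)
  if (metric == "plane") return(loc + exp(zeta) * rnorm(2))
  delta <- abs(exp(zeta) * rnorm(1))
  gamma <- runif(1, 0, 2 * pi)
  destination_point(loc, gamma, delta)
}

#' Great-circle destination point
#'
#' Point reached from `loc` (lon, lat in degrees) by travelling an arc
#' distance `delta` (radians, unit sphere) along initial bearing `gamma`
#' (radians, clockwise from north).
#'
#' @param loc length-2 (longitude, latitude) in degrees.
#' @param gamma bearing in radians.
#' @param delta arc distance in radians.
#' @return length-2 (longitude, latitude) in degrees, longitude in
#'   (-180, 180].
#' @export
destination_point <- function(loc, gamma, delta) {
  lam <- loc[1] * pi / 180; phi <- loc[2] * pi / 180
  phi2 <- asin(sin(phi) * cos(delta) + cos(phi) * sin(delta) * cos(gamma))
  lam2 <- lam + atan2(sin(gamma) * sin(delta) * cos(phi),
                      cos(delta) - sin(phi) * sin(phi2))
  lam2 <- (lam2 + pi) %% (2 * pi) - pi
  if (lam2 == -pi) lam2 <- pi
  c(lam2 * 180 / pi, phi2 * 180 / pi)
}

#' Adaptive proposal-scale update
#'
#' After each window of proposals of a parameter, its log proposal scale
#' `zeta` is nudged toward the value giving a 0.44 acceptance proportion
#' (optimal for one-dimensional proposals): increased by
#' `a = min(0.01, n^(-1/2))` if the window's acceptance proportion exceeded
#' 0.44, decreased by `a` otherwise (a proportion of exactly 0.44 counts as
#' "not greater"). `zeta` is clamped to `[-cap, cap]`.
#'
#' @param zeta current log proposal scale.
#' @param window_rate acceptance proportion in the last window.
#' @param n adaptation epoch index (1 for the first window of that
#'   parameter).
#' @param cap clamp for `zeta` (default 10).
#' @return updated `zeta`.
#' @export
adapt_tuning <- function(zeta, window_rate, n, cap = 10) {
  a <- min(0.01, 1 / sqrt(n))
  z <- if (window_rate > 0.44) zeta + a else zeta - a
  max(-cap, min(cap, z))
}

#' Draw an initial parameter state
#'
#' Scalars and nuggets are drawn from their priors; `w` is drawn from its
#' prior for admixture variants and fixed at 0 otherwise; `G` starts at the
#' prior location centers; `Gstar` starts at uniform coordinates within the
#' observed coordinate ranges. Redraws (up to `max_tries`) if the likelihood
#' is not finite at the initial state.
#'
#' @param cfg a [model_config()].
#' @param data a [standardize_freqs()] object (used to check the likelihood
#'   at the candidate state); may be `NULL` to skip the check.
#' @param max_tries redraw budget.
#' @return a state list with elements `a0, a1, a2, eta, w, G, Gstar`.
#' @export
init_state <- function(cfg, data = NULL, max_tries = 100L) {
  K <- cfg$K
  for (i in seq_len(max_tries)) {
    st <- list(
      a0 = rexp(1, cfg$rate_a0),
      a1 = rexp(1, cfg$rate_a1),
      a2 = runif(1, cfg$a2_bounds[1], cfg$a2_bounds[2]),
      eta = rexp(K, cfg$rate_eta),
      w = if (cfg$variant %in% c(3, 4)) {
        rbeta(K, cfg$w_beta[1], cfg$w_beta[2]) / 2
      } else rep(0, K),
      G = cfg$prior_G_mean,
      Gstar = cbind(runif(K, cfg$coord_box[1, 1], cfg$coord_box[1, 2]),
                    runif(K, cfg$coord_box[2, 1], cfg$coord_box[2, 2])))
    if (is.null(data)) return(st)
    ll <- state_loglik(st, data, cfg)
    if (is.finite(ll)) return(st)
  }
  stop("cannot initialize in support: likelihood not finite after ",
       max_tries, " prior draws")
}

state_loglik <- function(state, data, cfg) {
  os <- admixed_cov(state$G, state$Gstar, state$w, state$a0, state$a1,
                    state$a2, state$eta, data$Sbar, metric = cfg$metric)
  wishart_loglik(data$omega_hat, os, data$Psi, data$L_eff)
}

#' One Metropolis-Hastings update (reference implementation)
#'
#' Perturbs one randomly chosen free parameter block (for `eta`, `w`, `G`,
#' `Gstar` a single randomly selected population) and accepts with
#' probability `min(1, exp(delta log posterior))`. All proposals are
#' symmetric, so no Hastings correction appears. This plain-R implementation
#' defines the update semantics and backs the unit tests; long chains run
#' through the compiled engine in [run_mcmc()], whose states are checked
#' against this implementation's posterior computations.
#'
#' @param state a state list, optionally carrying `zeta` (log proposal
#'   scales, one per block), `accept`/`propose` counters, and cached
#'   `log_lik`/`log_prior`.
#' @param data a [standardize_freqs()] object.
#' @param cfg a [model_config()].
#' @return the updated state (same structure, counters advanced).
#' @export
mh_step <- function(state, data, cfg) {
  K <- cfg$K
  nb <- 3L + 4L * K
  if (is.null(state$zeta)) state$zeta <- rep(0, nb)
  if (is.null(state$accept)) state$accept <- integer(nb)
  if (is.null(state$propose)) state$propose <- integer(nb)
  if (is.null(state$log_lik)) state$log_lik <- state_loglik(state, data, cfg)
  if (is.null(state$log_prior)) state$log_prior <- log_prior(state, cfg)
  if (!is.finite(state$log_lik + state$log_prior)) {
    stop("current posterior is not finite: corrupted state")
  }

  ids <- free_block_ids(cfg)
  b <- ids[sample.int(length(ids), 1L)]
  cand <- state
  if (b == 0L) cand$a0 <- propose_scalar(state$a0, state$zeta[b + 1L])
  else if (b == 1L) cand$a1 <- propose_scalar(state$a1, state$zeta[b + 1L])
  else if (b == 2L) cand$a2 <- propose_scalar(state$a2, state$zeta[b + 1L])
  else if (b <= 2L + K) {
    k <- b - 2L
    cand$eta[k] <- propose_scalar(state$eta[k], state$zeta[b + 1L])
  } else if (b <= 2L + 2L * K) {
    k <- b - 2L - K
    cand$w[k] <- propose_scalar(state$w[k], state$zeta[b + 1L])
  } else if (b <= 2L + 3L * K) {
    k <- b - 2L - 2L * K
    cand$G[k, ] <- propose_location(state$G[k, ], state$zeta[b + 1L],
                                    cfg$metric)
  } else {
    k <- b - 2L - 3L * K
    cand$Gstar[k, ] <- propose_location(state$Gstar[k, ], state$zeta[b + 1L],
                                        cfg$metric)
  }

  state$propose[b + 1L] <- state$propose[b + 1L] + 1L
  lp_new <- log_prior(cand, cfg)
  if (is.finite(lp_new)) {
    ll_new <- state_loglik(cand, data, cfg)
    log_ratio <- (ll_new + lp_new) - (state$log_lik + state$log_prior)
    if (is.finite(log_ratio) && log(runif(1)) < log_ratio) {
      cand$log_lik <- ll_new
      cand$log_prior <- lp_new
      cand$accept <- state$accept
      cand$accept[b + 1L] <- cand$accept[b + 1L] + 1L
      cand$propose <- state$propose
      cand$zeta <- state$zeta
      return(cand)
    }
  }
  state
}
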