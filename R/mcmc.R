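#' Run an adaptive Metropolis-within-Gibbs chain
#'
#' Samples the posterior of the geogenetic-map model with the compiled
#' engine. Each iteration perturbs one randomly chosen free block (a decay
#' parameter, or a single population's nugget, admixture proportion,
#' location, or admixture-source location); proposal scales are tuned
#' adaptively toward a 0.44 acceptance proportion in windows of
#' `cfg$adapt_window` proposals per block (see [adapt_tuning()]).
#'
#' @param data a [standardize_freqs()] object.
#' @param cfg a [model_config()].
#' @param init optional initial state (see [init_state()]); drawn from the
#'   priors when absent.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called so
#'   the chain is fully reproducible.
#' @param zeta0 optional initial log proposal scales (default all 0).
#' @return An object of class `chain_trace`: thinned `samples` (one named
#'   column per model parameter, including fixed ones), `log_lik`,
#'   `log_prior`, `log_post`, tuning history `zeta_hist`, cumulative
#'   acceptance and proposal counts at each thinned sample (`acc_hist`,
#'   `prop_hist`), `final_state`, and the configuration echo.
#' @export
run_mcmc <- function(data, cfg, init = NULL, seed = NULL, zeta0 = NULL) {
  stopifnot(inherits(data, "std_freqs"), inherits(cfg, "model_config"))
  if (cfg$K != length(data$Sbar)) stop("config K does not match data")
  if (data$L_eff < cfg$K - 1L) {
    stop("insufficient loci for full-rank projected covariance")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- init_state(cfg, data)
  nb <- 3L + 4L * cfg$K
  if (is.null(zeta0)) zeta0 <- rep(0, nb)

  priors <- list(rate_a0 = cfg$rate_a0, rate_a1 = cfg$rate_a1,
                 rate_eta = cfg$rate_eta, a2_bounds = cfg$a2_bounds,
                 w_beta = cfg$w_beta, Gmu = cfg$prior_G_mean,
                 Gsmu = cfg$prior_Gstar_mean, sigma_G = cfg$sigma_G,
                 sigma_Gstar = cfg$sigma_Gstar)
  res <- .mcmc_engine(data$omega_hat, data$Psi, data$L_eff, data$Sbar,
                      init[c("a0", "a1", "a2", "eta", "w", "G", "Gstar")],
                      cfg$metric == "sphere", free_block_ids(cfg), priors,
                      cfg$n_iter, cfg$thin, cfg$adapt_window, cfg$zeta_cap,
                      zeta0)

  K <- cfg$K
  lab <- data$labels %||% sprintf("pop%02d", 1:K)
  colnames(res$samples) <- c(
    "alpha0", "alpha1", "alpha2", paste0("eta_", lab), paste0("w_", lab),
    paste0("G_", lab, "_x"), paste0("G_", lab, "_y"),
    paste0("Gs_", lab, "_x"), paste0("Gs_", lab, "_y"))
  colnames(res$zeta_hist) <- colnames(res$acc_hist) <-
    colnames(res$prop_hist) <- block_names(cfg)

  structure(
    list(samples = res$samples,
         log_lik = as.numeric(res$log_lik),
         log_prior = as.numeric(res$log_prior),
         log_post = as.numeric(res$log_lik) + as.numeric(res$log_prior),
         zeta_hist = res$zeta_hist,
         acc_hist = res$acc_hist, prop_hist = res$prop_hist,
         zeta = as.numeric(res$zeta),
         final_state = c(res$final_state,
                         list(log_lik = res$final_log_lik,
                              log_prior = res$final_log_prior)),
         labels = lab, cfg = cfg, seed = seed,
         iterations = cfg$n_iter, thin = cfg$thin),
    class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat("<chain_trace> variant ", x$cfg$variant, ": ",
      format(x$iterations, big.mark = ","), " iterations, ",
      nrow(x$samples), " thinned samples of ", ncol(x$samples),
      " parameters\n", sep = "")
  cat("  final log posterior: ", format(tail(x$log_post, 1)), "\n", sep = "")
  invisible(x)
}

#' Per-block acceptance proportions over a chain segment
#'
#' @param trace a [run_mcmc()] trace.
#' @param from,to fractions of the chain (by thinned sample index) delimiting
#'   the segment; defaults to the final quarter.
#' @return named vector of acceptance proportions (NA for blocks never
#'   proposed in the segment).
#' @export
acceptance_rates <- function(trace, from = 0.75, to = 1) {
  n <- nrow(trace$acc_hist)
  i0 <- max(1L, floor(from * n)); i1 <- max(i0, ceiling(to * n))
  da <- trace$acc_hist[i1, ] - trace$acc_hist[i0, ]
  dp <- trace$prop_hist[i1, ] - trace$prop_hist[i0, ]
  out <- da / dp
  out[dp == 0] <- NA_real_
  out
}

#' Extract a full parameter state from a thinned sample
#'
#' @param trace a [run_mcmc()] trace.
#' @param i thinned sample index.
#' @return a state list as used by [log_prior()] and [mh_step()].
#' @export
trace_state <- function(trace, i) {
  K <- trace$cfg$K
  s <- trace$samples[i, ]
  list(a0 = unname(s[1]), a1 = unname(s[2]), a2 = unname(s[3]),
       eta = unname(s[3 + 1:K]), w = unname(s[3 + K + 1:K]),
       G = cbind(unname(s[3 + 2 * K + 1:K]), unname(s[3 + 3 * K + 1:K])),
       Gstar = cbind(unname(s[3 + 4 * K + 1:K]), unname(s[3 + 5 * K + 1:K])))
}

#' Short-runs / long-run analysis protocol
#'
#' Runs `n_short` independent location-only (no admixture) chains, selects
#' the one whose final state has the highest posterior ("best short run"),
#' and initializes the long chain of the target variant from that state with
#' admixture proportions at 0 and admixture sources drawn uniformly in the
#' observed coordinate range. Returns the long chain's trace; the short-run
#' provenance (final posteriors, seeds, selected index) is attached as
#' `$protocol`.
#'
#' @param data a [standardize_freqs()] object.
#' @param cfg a [model_config()] for the target (long-run) model.
#' @param n_short number of short chains.
#' @param short_len,long_len iteration counts for the short and long chains.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @return a `chain_trace` for the long run, with `$protocol` provenance.
#' @export
run_protocol <- function(data, cfg, n_short = 5L, short_len = 1e5,
                         long_len = 1e6, seed = 1L) {
  stopifnot(n_short >= 1L)
  short_variant <- if (cfg$variant %in% c(2, 4)) 2L else 1L
  scfg <- cfg
  scfg$variant <- short_variant
  scfg$free_types <- switch(short_variant, c("a0", "a1", "a2", "eta"),
                            c("a0", "a1", "a2", "eta", "G"))
  scfg$n_iter <- short_len
  scfg$thin <- max(1, floor(short_len / 100))

  seeds <- (as.integer(seed) + 104729L * seq_len(n_short + 1L)) %% 2147483647L
  shorts <- lapply(seq_len(n_short), function(i) {
    run_mcmc(data, scfg, seed = seeds[i])
  })
  finals <- vapply(shorts, function(tr) {
    tr$final_state$log_lik + tr$final_state$log_prior
  }, numeric(1))
  best <- which.max(finals)

  set.seed(seeds[n_short + 1L])
  K <- cfg$K
  init <- shorts[[best]]$final_state[c("a0", "a1", "a2", "eta", "w", "G",
                                       "Gstar")]
  init$w <- rep(0, K)
  init$Gstar <- cbind(
    runif(K, cfg$coord_box[1, 1], cfg$coord_box[1, 2]),
    runif(K, cfg$coord_box[2, 1], cfg$coord_box[2, 2]))
  lcfg <- cfg
  lcfg$n_iter <- long_len
  long <- run_mcmc(data, lcfg, init = init)
  long$protocol <- list(n_short = n_short, short_len = short_len,
                        short_final_log_post = finals, best_short = best,
                        seeds = seeds, master_seed = seed)
  long
}
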