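Package: mapmix
Title: Geogenetic Maps of Population Structure and Admixture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference of geogenetic maps: population locations on a
    two-dimensional surface whose pairwise distances predict allele-frequency
    covariance under a powered-exponential decay, with long-distance admixture
    sources and proportions co-estimated and drawn as arrows on the map.
    Includes the standardized sample covariance and its rank-correcting
    projection, a projected Wishart likelihood, an adaptive
    Metropolis-within-Gibbs sampler with a short-runs/long-run analysis
    protocol, Procrustes-aligned map summaries, and a lattice stepping-stone
    coalescent simulator (msprime backend) plus an exact multivariate-normal
    generator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
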