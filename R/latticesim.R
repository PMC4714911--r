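#' Canonical stepping-stone lattice scenarios
#'
#' Builds a simulation scenario on a full lattice of demes (default 11 rows x
#' 9 columns) with symmetric migration to the four nearest neighbors at rate
#' `m` and to the four diagonal neighbors at rate `m/2`, sampled at every
#' other deme (odd rows and columns), giving 30 sampled populations on a
#' 6 x 5 grid numbered row-major from the southwest corner (population 1 =
#' SW, population 30 = NE; populations 24, 25 and 29 are the sampled
#' neighbors of 30).
#'
#' Kinds:
#' \describe{
#'   \item{homogeneous}{uniform migration, no events.}
#'   \item{barrier}{migration across the grid's central boundary (between
#'     full-lattice rows 6 and 7) divided by `barrier_divisor` (default 5).}
#'   \item{expansion}{the last five full-lattice columns expanded in the
#'     immediate past from the column just west of the expanded block, within
#'     each row.}
#'   \item{corner_admixture}{population 30 draws half of its ancestry from
#'     population 1 immediately before sampling.}
#'   \item{barrier_admixture}{barrier plus a cross-barrier ancestry pulse:
#'     `design = "inland"` sends 10% into population 23 (one sampled row from
#'     the barrier) from population 13 across it; `design = "neighbor"` sends
#'     40% into population 18 (adjacent to the barrier) from population 13
#'     directly across.}
#' }
#'
#' @param kind scenario name (above).
#' @param design for `barrier_admixture`: `"inland"` or `"neighbor"`.
#' @param n_row,n_col full-lattice dimensions.
#' @param m nearest-neighbor backward migration rate (coalescent scale, deme
#'   size 1; the default 0.25 corresponds to 4Nm = 1 between adjacent
#'   demes).
#' @param m_diag diagonal migration rate (default `m/2`).
#' @param barrier_divisor cross-barrier rate divisor.
#' @param n_loci number of unlinked single-segregating-site loci.
#' @param haploids_per_deme haploid sample size per sampled deme.
#' @param deme_size per-deme coalescent size.
#' @param event_time scaled time of "immediate past" events.
#' @return An object of class `sim_scenario`.
#' @export
build_scenario <- function(kind = c("homogeneous", "barrier", "expansion",
                                    "corner_admixture", "barrier_admixture"),
                           design = c("inland", "neighbor"),
                           n_row = 11L, n_col = 9L, m = 0.25,
                           m_diag = m / 2, barrier_divisor = 5,
                           n_loci = 10000L, haploids_per_deme = 10L,
                           deme_size = 1, event_time = 1e-6) {
  kind <- match.arg(kind)
  design <- match.arg(design)

  srows <- seq(1L, n_row, by = 2L)
  scols <- seq(1L, n_col, by = 2L)
  deme0 <- function(r, c) (r - 1L) * n_col + (c - 1L)  # 0-based, row-major SW
  # population p = (sampled_row - 1) * n_sampled_cols + sampled_col,
  # rows numbered south -> north, columns west -> east
  sampled <- as.vector(vapply(srows, function(r) deme0(r, scols),
                              integer(length(scols))))
  K <- length(sampled)
  # planar coordinates of the sampled demes (x = column, y = row)
  locations <- cbind(x = rep(scols, times = length(srows)),
                     y = rep(srows, each = length(scols)))

  pop_deme <- function(p) sampled[p]  # sampled population index -> 0-based deme

  barrier_row <- 0L
  events <- list()
  if (kind %in% c("barrier", "barrier_admixture")) {
    barrier_row <- as.integer(floor(n_row / 2) + 1L)  # between rows 6 and 7
  }
  if (kind == "corner_admixture") {
    events <- list(list(type = "mass_migration", time = event_time,
                        source_deme = pop_deme(K), dest_deme = pop_deme(1L),
                        proportion = 0.5))
  }
  if (kind == "barrier_admixture") {
    recip <- if (design == "inland") 23L else 18L
    prop <- if (design == "inland") 0.10 else 0.40
    events <- list(list(type = "mass_migration", time = event_time,
                        source_deme = pop_deme(recip),
                        dest_deme = pop_deme(13L), proportion = prop))
  }
  if (kind == "expansion") {
    dcols <- seq(n_col - 4L, n_col)
    parent <- min(dcols) - 1L
    if (parent < 1L) stop("lattice too narrow for the expansion design")
    events <- lapply(as.vector(outer(dcols, seq_len(n_row),
                                     function(c, r) c + 1000L * r)), function(code) {
      r <- code %/% 1000L; c <- code %% 1000L
      list(type = "merge", time = event_time,
           source_deme = deme0(r, c), dest_deme = deme0(r, parent),
           proportion = 1)
    })
  }

  structure(
    list(kind = kind, design = if (kind == "barrier_admixture") design,
         n_row = as.integer(n_row), n_col = as.integer(n_col),
         deme_size = deme_size, m = m, m_diag = m_diag,
         barrier_row = barrier_row, barrier_divisor = barrier_divisor,
         events = events, sampled_demes = sampled,
         haploids_per_deme = as.integer(haploids_per_deme),
         n_loci = as.integer(n_loci), locations = locations,
         labels = sprintf("pop%02d", seq_len(K))),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$kind,
      if (!is.null(x$design)) paste0(" (", x$design, ")"),
      ": ", x$n_row, "x", x$n_col, " lattice, ",
      length(x$sampled_demes), " sampled demes, ", x$n_loci, " loci\n",
      sep = "")
  invisible(x)
}

python_binary <- function() {
  py <- getOption("mapmix.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no python interpreter found; the lattice coalescent uses the ",
         "msprime backend (set options(mapmix.python = ...) if needed)")
  }
  py
}

#' Simulate allele counts under a lattice scenario
#'
#' Runs the structured coalescent on the lattice (msprime backend): for each
#' locus an independent genealogy of all sampled haploids is generated, and
#' one mutation is placed uniformly on the genealogy's total branch length,
#' so every locus carries exactly one segregating site and is polymorphic in
#' the pooled sample. Admixture pulses and expansions are mass movements of
#' lineages at their scaled event times.
#'
#' @param scn a [build_scenario()] object.
#' @param seed integer seed (passed to the backend; identical seeds give
#'   identical data).
#' @return an [allele_counts()] object with planar deme coordinates attached.
#' @export
simulate_counts <- function(scn, seed = 1L) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (scn$m <= 0 && scn$m_diag <= 0 && length(scn$sampled_demes) > 1L) {
    stop("disconnected lattice: migration rates are zero, sampled demes ",
         "cannot share a common ancestor")
  }
  script <- system.file("python", "lattice_coalescent.py", package = "mapmix",
                        mustWork = TRUE)
  cfg <- list(n_row = scn$n_row, n_col = scn$n_col,
              deme_size = scn$deme_size, m = scn$m, m_diag = scn$m_diag,
              barrier_row = scn$barrier_row,
              barrier_divisor = scn$barrier_divisor,
              events = scn$events, sampled_demes = as.list(scn$sampled_demes),
              haploids_per_deme = scn$haploids_per_deme,
              n_loci = scn$n_loci, seed = as.integer(seed))
  cfg_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(cfg_file, out_file)), add = TRUE)
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  status <- system2(python_binary(), c(script, cfg_file, out_file),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(out_file)) {
    stop("coalescent backend failed:\n", paste(status, collapse = "\n"))
  }
  counts <- as.matrix(read.table(out_file, sep = "\t", header = FALSE))
  dimnames(counts) <- NULL
  K <- length(scn$sampled_demes)
  sizes <- matrix(scn$haploids_per_deme, K, scn$n_loci)
  allele_counts(counts, sizes, labels = scn$labels,
                locations = scn$locations)
}

#' Exact model-faithful Gaussian data generator
#'
#' Draws `L` independent zero-mean Gaussian vectors with the parametric
#' (optionally admixed) covariance, mean-centers them with the centering
#' matrix implied by `Sbar`, and packages the result as standardized data.
#' This bypasses the binomial sampling layer entirely, so posterior
#' calibration of the sampler can be checked against data generated exactly
#' under the likelihood's model.
#'
#' @param G K x 2 population locations.
#' @param a0,a1,a2 decay parameters.
#' @param eta nugget vector.
#' @param Sbar mean sample sizes.
#' @param L number of loci.
#' @param w,Gstar optional admixture proportions and source locations
#'   (defaults: no admixture).
#' @param metric `"plane"` or `"sphere"`.
#' @param labels optional population labels.
#' @return a `std_freqs` object (as from [standardize_freqs()]).
#' @export
simulate_mvn <- function(G, a0, a1, a2, eta, Sbar, L, w = NULL, Gstar = NULL,
                         metric = c("plane", "sphere"), labels = NULL) {
  metric <- match.arg(metric)
  G <- as.matrix(G)
  K <- nrow(G)
  if (is.null(w)) w <- rep(0, K)
  if (is.null(Gstar)) Gstar <- G
  os <- admixed_cov(G, Gstar, w, a0, a1, a2, eta, Sbar, metric = metric)
  cc <- tryCatch(chol(os), error = function(e) NULL)
  if (is.null(cc)) stop("model covariance is not positive definite")
  Y <- crossprod(cc, matrix(rnorm(K * L), K, L))
  T_mat <- centering_matrix(Sbar)
  Xhat <- T_mat %*% Y
  if (is.null(labels)) labels <- sprintf("pop%02d", seq_len(K))
  structure(
    list(Xhat = Xhat, fbar = rep(NA_real_, L), Sbar = Sbar, T_mat = T_mat,
         Psi = projection_matrix(T_mat), omega_hat = tcrossprod(Xhat) / L,
         L_eff = L, dropped = data.frame(locus = integer(0),
                                         reason = character(0)),
         labels = labels, locations = G),
    class = "std_freqs")
}
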