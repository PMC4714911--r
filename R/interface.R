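#' Read count and size matrices (and optional coordinates) from TSV
#'
#' The canonical interchange format: tab-separated matrices with population
#' labels as row names and loci as columns, plus an optional coordinates
#' table with columns `population`, `longitude`, `latitude` (or `x`, `y`).
#' Population order is taken from the counts file; coordinates are joined by
#' label.
#'
#' @param counts_path,sizes_path TSV matrix paths.
#' @param coords_path optional coordinates TSV path.
#' @return an [allele_counts()] object.
#' @export
read_count_matrices <- function(counts_path, sizes_path, coords_path = NULL) {
  for (p in c(counts_path, sizes_path, coords_path)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  C <- as.matrix(read.table(counts_path, sep = "\t", header = FALSE,
                            row.names = 1, check.names = FALSE))
  S <- as.matrix(read.table(sizes_path, sep = "\t", header = FALSE,
                            row.names = 1, check.names = FALSE))
  if (!all(dim(C) == dim(S))) {
    stop("counts (", nrow(C), "x", ncol(C), ") and sizes (", nrow(S), "x",
         ncol(S), ") matrices have different shapes")
  }
  if (!identical(rownames(C), rownames(S))) {
    stop("counts and sizes files list different populations")
  }
  locations <- NULL
  if (!is.null(coords_path)) {
    co <- read.table(coords_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    names(co) <- tolower(names(co))
    xcol <- intersect(c("longitude", "x"), names(co))[1]
    ycol <- intersect(c("latitude", "y"), names(co))[1]
    if (is.na(xcol) || is.na(ycol) || !"population" %in% names(co)) {
      stop("coordinates file needs columns population, longitude/x, latitude/y")
    }
    missing <- setdiff(rownames(C), co$population)
    if (length(missing) > 0L) {
      stop("coordinates file is missing population(s): ",
           paste(missing, collapse = ", "))
    }
    co <- co[match(rownames(C), co$population), ]
    locations <- cbind(co[[xcol]], co[[ycol]])
  }
  allele_counts(C, S, labels = rownames(C), locations = locations)
}

#' Write allele counts to TSV
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_sizes.tsv`, and (when coordinates
#' are present) `<prefix>_coords.tsv` in the format read by
#' [read_count_matrices()].
#'
#' @param ac an [allele_counts()] object.
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
write_allele_counts <- function(ac, prefix) {
  stopifnot(inherits(ac, "allele_counts"))
  paths <- paste0(prefix, c("_counts.tsv", "_sizes.tsv"))
  write.table(ac$counts, paths[1], sep = "\t", quote = FALSE,
              col.names = FALSE)
  write.table(ac$sizes, paths[2], sep = "\t", quote = FALSE,
              col.names = FALSE)
  if (!is.null(ac$locations)) {
    p <- paste0(prefix, "_coords.tsv")
    write.table(data.frame(population = ac$labels,
                           longitude = ac$locations[, 1],
                           latitude = ac$locations[, 2]),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write standardized data summaries to TSV
#'
#' Exports the sample covariance matrix, the per-population mean sample
#' sizes, and the dropped-locus log of a [standardize_freqs()] object.
#'
#' @param sf a `std_freqs` object.
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
write_std_freqs <- function(sf, prefix) {
  stopifnot(inherits(sf, "std_freqs"))
  paths <- paste0(prefix, c("_covariance.tsv", "_sizes.tsv", "_dropped.tsv"))
  om <- sf$omega_hat
  dimnames(om) <- list(sf$labels, sf$labels)
  write.table(om, paths[1], sep = "\t", quote = FALSE)
  write.table(data.frame(population = sf$labels, mean_size = sf$Sbar),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sf$dropped, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Write a chain trace and its run metadata
#'
#' The trace is a TSV with one row per thinned sample (all parameters plus
#' log likelihood/prior/posterior); a JSON sidecar records the configuration
#' echo, seed and acceptance summaries, sufficient to reproduce the run.
#'
#' @param trace a [run_mcmc()] trace.
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "chain_trace"))
  tab <- data.frame(trace$samples, check.names = FALSE)
  tab$log_lik <- trace$log_lik
  tab$log_prior <- trace$log_prior
  tab$log_post <- trace$log_post
  tsv <- paste0(prefix, "_trace.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    variant = trace$cfg$variant, K = trace$cfg$K, metric = trace$cfg$metric,
    iterations = trace$iterations, thin = trace$thin, seed = trace$seed,
    location_prior = trace$cfg$location_prior,
    sigma_G = trace$cfg$sigma_G, sigma_Gstar = trace$cfg$sigma_Gstar,
    acceptance_final_quarter = as.list(round(acceptance_rates(trace), 4)),
    protocol = trace$protocol,
    package_version = as.character(utils::packageVersion("mapmix")))
  js <- paste0(prefix, "_run.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(tsv, js))
}

cli_usage <- function() {
  cat("usage: mapmix <command> [options]\n",
      "commands:\n",
      "  simulate --kind K [--design D] --out PREFIX [--loci N] [--seed S]\n",
      "  run      --counts F --sizes F [--coords F] --out PREFIX\n",
      "           [--variant 1-4] [--metric plane|sphere] [--seed S]\n",
      "           [--n-short N] [--short-len N] [--long-len N] [--thin N]\n",
      "           [--location-prior observed|random]\n",
      "  map      --trace PREFIX --out PREFIX [--burn F] [--figure PATH]\n",
      "  validate --counts F --sizes F [--coords F]\n", sep = "")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("option ", a, " needs a value")
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Implements the `simulate`, `run`, `map` and `validate` subcommands used by
#' the installed `exec/mapmix` script; run it with no arguments for the flag
#' summary. Returns an exit code rather than calling `quit()`, so it is
#' testable in-process.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success, 2 on usage errors).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(2L) }
  cmd <- args[1]
  opts <- tryCatch(cli_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts)); cli_usage(); return(2L)
  }
  seed <- as.integer(opts$seed %||% 1L)

  if (cmd == "simulate") {
    if (is.null(opts$kind) || is.null(opts$out)) { cli_usage(); return(2L) }
    scn <- build_scenario(kind = opts$kind,
                          design = opts$design %||% "inland",
                          n_loci = as.integer(opts$loci %||% 10000L))
    ac <- simulate_counts(scn, seed = seed)
    write_allele_counts(ac, opts$out)
    jsonlite::write_json(list(kind = scn$kind, seed = seed,
                              n_loci = scn$n_loci,
                              package_version =
                                as.character(utils::packageVersion("mapmix"))),
                         paste0(opts$out, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message("wrote ", opts$out, "_{counts,sizes,coords}.tsv")
    return(0L)
  }

  if (cmd == "validate" || cmd == "run") {
    if (is.null(opts$counts) || is.null(opts$sizes)) { cli_usage(); return(2L) }
    ac <- read_count_matrices(opts$counts, opts$sizes, opts$coords)
    if (cmd == "validate") {
      message("OK: ", nrow(ac$counts), " populations x ", ncol(ac$counts),
              " loci", if (!is.null(ac$locations)) " with coordinates")
      return(0L)
    }
    if (is.null(opts$out)) { cli_usage(); return(2L) }
    data <- standardize_freqs(ac)
    set.seed(seed)
    cfg <- model_config(variant = as.integer(opts$variant %||% 4L),
                        obs_locations = ac$locations, K = nrow(ac$counts),
                        metric = opts$metric %||% "plane",
                        location_prior = opts$location_prior %||% "observed",
                        thin = as.integer(opts$thin %||% 1000L))
    trace <- run_protocol(data, cfg,
                          n_short = as.integer(opts$n_short %||% 5L),
                          short_len = as.numeric(opts$short_len %||% 1e5),
                          long_len = as.numeric(opts$long_len %||% 1e6),
                          seed = seed)
    write_trace(trace, opts$out)
    message("wrote ", opts$out, "_trace.tsv")
    return(0L)
  }

  if (cmd == "map") {
    if (is.null(opts$trace) || is.null(opts$out)) { cli_usage(); return(2L) }
    tab <- read.table(paste0(opts$trace, "_trace.tsv"), sep = "\t",
                      header = TRUE, check.names = FALSE)
    trace <- trace_from_table(tab)
    map <- summarize_map(trace, burn_in_fraction =
                           as.numeric(opts$burn %||% 0.5))
    write.table(as.data.frame(map), paste0(opts$out, "_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(opts$figure)) render_map(map, opts$figure)
    message("wrote ", opts$out, "_map.tsv")
    return(0L)
  }

  message("unknown command: ", cmd)
  cli_usage()
  2L
}

# rebuild a minimal chain_trace from a persisted trace table
trace_from_table <- function(tab) {
  parcols <- setdiff(names(tab), c("log_lik", "log_prior", "log_post"))
  K <- (length(parcols) - 3L) / 6L
  labels <- sub("^eta_", "", grep("^eta_", parcols, value = TRUE))
  samples <- as.matrix(tab[, parcols])
  structure(
    list(samples = samples, log_lik = tab$log_lik,
         log_prior = tab$log_prior, log_post = tab$log_post,
         labels = labels, cfg = list(K = as.integer(K))),
    class = "chain_trace")
}
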