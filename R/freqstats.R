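#' Allele count data for a set of populations
#'
#' Bundles the counted-allele matrix `C` and the sample-size matrix `S`
#' (populations in rows, biallelic loci in columns) together with population
#' labels and, optionally, observed sampling coordinates.
#'
#' @param counts integer matrix, K populations x L loci: number of copies of
#'   the (arbitrarily chosen) counted allele.
#' @param sizes integer matrix of the same shape: total alleles typed.
#' @param labels character vector of K population labels; defaults to the
#'   rownames of `counts` or `pop01...popK`.
#' @param locations optional K x 2 matrix/data.frame of observed coordinates
#'   (longitude, latitude in degrees for spherical analyses, or x/y in plane
#'   units for abstract landscapes).
#' @return An object of class `allele_counts`.
#' @examples
#' C <- rbind(c(1, 2), c(3, 1))
#' S <- matrix(4, 2, 2)
#' ac <- allele_counts(C, S)
#' @export
allele_counts <- function(counts, sizes, labels = NULL, locations = NULL) {
  counts <- as.matrix(counts)
  sizes <- as.matrix(sizes)
  if (!all(dim(counts) == dim(sizes))) {
    stop("counts and sizes must have identical dimensions (got ",
         paste(dim(counts), collapse = "x"), " vs ",
         paste(dim(sizes), collapse = "x"), ")")
  }
  K <- nrow(counts); L <- ncol(counts)
  if (K < 2L) stop("need at least 2 populations")
  if (L < 1L) stop("need at least 1 locus")
  if (any(counts < 0) || any(sizes < 0)) stop("counts and sizes must be nonnegative")
  bad <- which(counts > sizes, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("counts exceed sizes at population ", bad[1, 1], " (",
         rownames(counts)[bad[1, 1]] %||% bad[1, 1], "), locus ", bad[1, 2])
  }
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- sprintf("pop%02d", seq_len(K))
  if (length(labels) != K) stop("labels must have length K = ", K)
  if (!is.null(locations)) {
    locations <- as.matrix(locations)
    if (nrow(locations) != K || ncol(locations) != 2L) {
      stop("locations must be a K x 2 matrix of (longitude, latitude)")
    }
    storage.mode(locations) <- "double"
    rownames(locations) <- labels
  }
  rownames(counts) <- rownames(sizes) <- labels
  structure(
    list(counts = counts, sizes = sizes, labels = labels,
         locations = locations),
    class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("<allele_counts> ", nrow(x$counts), " populations x ",
      ncol(x$counts), " loci", if (!is.null(x$locations)) "; with coordinates",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-centering matrix
#'
#' The linear operator that subtracts the size-weighted mean frequency across
#' populations from each population's frequency: `T[i,j] = d_ij - Sbar_j /
#' sum(Sbar)`. Rows sum to zero; `T %*% rep(1, K)` is the zero vector; the
#' matrix has rank K-1.
#'
#' @param Sbar positive numeric vector of per-population mean sample sizes.
#' @return K x K centering matrix.
#' @export
centering_matrix <- function(Sbar) {
  if (any(!is.finite(Sbar)) || any(Sbar <= 0)) {
    stop("all mean sample sizes must be positive and finite")
  }
  K <- length(Sbar)
  diag(K) - matrix(rep(Sbar / sum(Sbar), each = K), K, K)
}

#' Orthonormal projection onto the centered subspace
#'
#' Returns a K x (K-1) matrix with orthonormal columns spanning the column
#' space of the centering matrix `T`, obtained by dropping the last column of
#' the orthogonal factor in the QR decomposition of `T`. The sign of each
#' column is fixed so the corresponding diagonal element of the triangular
#' factor is nonnegative, making the result reproducible; the projected
#' Wishart likelihood is invariant to this (or any other orthonormal) choice
#' of basis.
#'
#' @param T_mat a centering matrix as built by [centering_matrix()].
#' @return K x (K-1) projection matrix `Psi` with `t(Psi) %*% Psi = I`.
#' @export
projection_matrix <- function(T_mat) {
  K <- nrow(T_mat)
  qrT <- qr(T_mat)
  R <- qr.R(qrT)
  d <- diag(R)
  if (any(abs(d[seq_len(K - 1L)]) < 1e-10)) {
    stop("centering matrix is rank deficient beyond K-1 (degenerate weights)")
  }
  Q <- qr.Q(qrT)
  s <- ifelse(d[seq_len(K - 1L)] >= 0, 1, -1)
  Q[, seq_len(K - 1L), drop = FALSE] %*% diag(s, K - 1L)
}

#' Standardize allele frequencies and form the sample covariance
#'
#' Computes, per retained locus, the size-weighted global mean frequency
#' `fbar_l = sum_k C[k,l] / sum_k S[k,l]` and the standardized frequencies
#' `Xhat[k,l] = (fhat[k,l] - fbar_l) / sqrt(fbar_l (1 - fbar_l))`, then the
#' K x K sample covariance `Omega_hat = Xhat %*% t(Xhat) / L_eff`, the
#' centering matrix `T` and projection `Psi` used by the likelihood.
#'
#' Loci are dropped (and recorded with reasons) when any population has zero
#' sample size at the locus, or when the pooled minor-allele count is below
#' `min_minor_count` (monomorphic loci always fall in this class: the
#' standardization is undefined at pooled frequency 0 or 1).
#'
#' @param ac an [allele_counts()] object.
#' @param min_minor_count drop loci whose pooled minor-allele count is below
#'   this (default 1, i.e. drop only monomorphic loci).
#' @return An object of class `std_freqs` with elements `Xhat`, `fbar`,
#'   `Sbar`, `T_mat`, `Psi`, `omega_hat`, `L_eff`, `dropped` (data.frame of
#'   locus index and reason), `labels`, `locations`.
#' @export
standardize_freqs <- function(ac, min_minor_count = 1L) {
  stopifnot(inherits(ac, "allele_counts"))
  C <- ac$counts; S <- ac$sizes
  K <- nrow(C)

  miss <- colSums(S == 0) > 0
  pooledC <- colSums(C); pooledS <- colSums(S)
  minor <- pmin(pooledC, pooledS - pooledC)
  low <- !miss & minor < min_minor_count
  drop <- miss | low
  if (any(miss)) {
    warning(sum(miss), " locus/loci dropped: zero sample size in some population")
  }
  dropped <- data.frame(
    locus = which(drop),
    reason = ifelse(miss[drop], "zero sample size",
                    "pooled minor count below threshold"))
  keep <- which(!drop)
  L_eff <- length(keep)
  if (L_eff == 0L) stop("no usable loci after filtering")

  C <- C[, keep, drop = FALSE]; S <- S[, keep, drop = FALSE]
  fhat <- C / S
  fbar <- colSums(C) / colSums(S)
  Xhat <- sweep(fhat, 2L, fbar, "-") /
    matrix(sqrt(fbar * (1 - fbar)), K, L_eff, byrow = TRUE)

  Sbar <- rowMeans(S)
  if (max(Sbar) / min(Sbar) > 5) {
    warning("large differences in mean sample sizes across populations ",
            "(max/min > 5); the shared centering matrix is a poor approximation")
  }
  T_mat <- centering_matrix(Sbar)
  Psi <- projection_matrix(T_mat)
  omega_hat <- tcrossprod(Xhat) / L_eff

  structure(
    list(Xhat = Xhat, fbar = fbar, Sbar = Sbar, T_mat = T_mat, Psi = Psi,
         omega_hat = omega_hat, L_eff = L_eff, dropped = dropped,
         labels = ac$labels, locations = ac$locations),
    class = "std_freqs")
}

#' @export
print.std_freqs <- function(x, ...) {
  cat("<std_freqs> ", length(x$Sbar), " populations, ", x$L_eff,
      " retained loci (", nrow(x$dropped), " dropped)\n", sep = "")
  invisible(x)
}
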