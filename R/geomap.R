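#' Maximum a posteriori state of a chain
#'
#' Returns the post-burn-in thinned sample with the highest recorded log
#' posterior (ties broken by the earliest index).
#'
#' @param trace a [run_mcmc()] trace.
#' @param burn_in_fraction fraction of thinned samples discarded first
#'   (default 0.5).
#' @return list: the `state` (see [trace_state()]), its thinned `index`, and
#'   `log_post`.
#' @export
map_estimate <- function(trace, burn_in_fraction = 0.5) {
  n <- length(trace$log_post)
  if (n < 1L) stop("empty trace")
  if (burn_in_fraction >= 1) stop("burn-in fraction must be below 1")
  from <- min(n, floor(burn_in_fraction * n) + 1L)
  idx <- seq(from, n)
  best <- idx[which.max(trace$log_post[idx])]
  list(state = trace_state(trace, best), index = best,
       log_post = trace$log_post[best])
}

#' Full Procrustes superimposition
#'
#' Least-squares rotation, dilation and translation of `source` onto
#' `reference` (both n x 2). Reflection is permitted by default — the
#' likelihood depends only on pairwise distances and cannot distinguish
#' chirality — and can be disabled.
#'
#' @param source,reference n x 2 coordinate matrices.
#' @param allow_reflection logical.
#' @return An object of class `procrustes_fit`: `rotation` (2 x 2
#'   orthogonal), `scale`, `translation` (length 2), `rss` (residual sum of
#'   squares). Apply with [apply_procrustes()].
#' @export
procrustes_fit <- function(source, reference, allow_reflection = TRUE) {
  X <- as.matrix(source); Y <- as.matrix(reference)
  if (nrow(X) != nrow(Y) || ncol(X) != 2L || ncol(Y) != 2L) {
    stop("source and reference must be n x 2 with matching n")
  }
  if (nrow(X) < 2L) stop("need at least 2 points")
  if (all(apply(Y, 2, sd) == 0)) stop("degenerate reference: all points identical")
  if (all(apply(X, 2, sd) == 0)) stop("degenerate source: all points identical")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  M <- crossprod(Xc, Yc)            # 2 x 2
  sv <- svd(M)
  sgn <- c(1, 1)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) sgn <- c(1, -1)
  R <- sv$u %*% diag(sgn) %*% t(sv$v)       # so Xc %*% R best matches Yc
  s <- sum(sv$d * sgn) / sum(Xc^2)
  t_vec <- my - s * as.numeric(mx %*% R)
  fitted <- s * X %*% R + matrix(t_vec, nrow(X), 2, byrow = TRUE)
  structure(
    list(rotation = R, scale = s, translation = t_vec,
         rss = sum((fitted - Y)^2)),
    class = "procrustes_fit")
}

#' Apply a Procrustes fit to coordinates
#'
#' @param fit a [procrustes_fit()].
#' @param X n x 2 coordinates.
#' @return transformed n x 2 coordinates.
#' @export
apply_procrustes <- function(fit, X) {
  X <- as.matrix(X)
  fit$scale * X %*% fit$rotation +
    matrix(fit$translation, nrow(X), 2, byrow = TRUE)
}

#' Summarize a chain into a geogenetic map
#'
#' Extracts the MAP state, Procrustes-aligns its locations to the reference
#' coordinates when supplied (the fit is computed on the population locations
#' `G` only and then applied to the admixture sources `Gstar`, so sources
#' cannot distort the frame), computes equal-tailed credible intervals and
#' posterior means for the admixture proportions, and builds per-population
#' 95% location ellipses from the post-burn-in draws (each draw is itself
#' Procrustes-aligned to the MAP configuration first, so rotational drift of
#' the whole map does not inflate the ellipses). Alignment treats the 2-D
#' coordinates as planar, a presentation-layer approximation for spherical
#' chains.
#'
#' @param trace a [run_mcmc()] trace.
#' @param burn_in_fraction fraction of thinned samples discarded.
#' @param reference optional K x 2 observed coordinates to align to.
#' @param allow_reflection passed to [procrustes_fit()].
#' @return An object of class `geogenetic_map` with `G`, `Gstar`, `w_mean`,
#'   `w_lo`, `w_hi`, `ellipses` (per-population list of center, 2x2
#'   covariance, 95% radius scaling), `labels`, `map_state`.
#' @export
summarize_map <- function(trace, burn_in_fraction = 0.5, reference = NULL,
                          allow_reflection = TRUE) {
  if (burn_in_fraction >= 1) stop("burn-in fraction must be below 1")
  K <- trace$cfg$K
  mp <- map_estimate(trace, burn_in_fraction)
  G <- mp$state$G
  Gs <- mp$state$Gstar

  if (!is.null(reference)) {
    fit <- procrustes_fit(G, reference, allow_reflection = allow_reflection)
    G <- apply_procrustes(fit, G)
    Gs <- apply_procrustes(fit, Gs)
  } else {
    fit <- NULL
  }

  n <- length(trace$log_post)
  idx <- seq(min(n, floor(burn_in_fraction * n) + 1L), n)
  wcols <- trace$samples[idx, 3 + K + 1:K, drop = FALSE]
  w_mean <- colMeans(wcols)
  w_lo <- apply(wcols, 2, quantile, 0.025, names = FALSE)
  w_hi <- apply(wcols, 2, quantile, 0.975, names = FALSE)

  # per-draw alignment to the MAP configuration for location uncertainty
  Gmap <- mp$state$G
  aligned <- lapply(idx, function(i) {
    st <- trace_state(trace, i)
    f <- procrustes_fit(st$G, Gmap, allow_reflection = allow_reflection)
    A <- apply_procrustes(f, st$G)
    if (!is.null(fit)) A <- apply_procrustes(fit, A)
    A
  })
  ellipses <- lapply(seq_len(K), function(k) {
    P <- t(vapply(aligned, function(A) A[k, ], numeric(2)))
    list(center = colMeans(P),
         cov = if (nrow(P) > 2) cov(P) else diag(0, 2),
         level_radius = sqrt(qchisq(0.95, df = 2)))
  })

  structure(
    list(G = G, Gstar = Gs, w_mean = w_mean, w_lo = w_lo, w_hi = w_hi,
         ellipses = ellipses, labels = trace$labels, map_state = mp,
         alignment = fit, burn_in_fraction = burn_in_fraction),
    class = "geogenetic_map")
}

#' @export
print.geogenetic_map <- function(x, ...) {
  cat("<geogenetic_map> ", length(x$labels), " populations; ",
      sum(x$w_mean > 0.01), " with posterior mean admixture > 0.01\n", sep = "")
  invisible(x)
}

#' Tabular form of a geogenetic map
#'
#' @param x a [summarize_map()] object.
#' @param ... unused.
#' @return data.frame with population, eastings/northings of locations and
#'   sources, and admixture summaries.
#' @export
as.data.frame.geogenetic_map <- function(x, ...) {
  data.frame(population = x$labels,
             easting = x$G[, 1], northing = x$G[, 2],
             source_easting = x$Gstar[, 1], source_northing = x$Gstar[, 2],
             w_mean = x$w_mean, w_lo = x$w_lo, w_hi = x$w_hi,
             row.names = NULL)
}

#' Plot a geogenetic map
#'
#' Population labels at their inferred locations, with admixture arrows from
#' each source to its recipient; arrow width and opacity are proportional to
#' the posterior mean admixture proportion, and arrows are suppressed below
#' `w_threshold`. Axes are labeled Eastings/Northings: the map lives in
#' geogenetic, not geographic, space.
#'
#' @param x a [summarize_map()] object.
#' @param w_threshold suppress arrows for populations whose posterior mean
#'   admixture proportion is below this (default 0.01).
#' @param ellipses draw 95% location ellipses.
#' @param ... unused.
#' @export
plot.geogenetic_map <- function(x, w_threshold = 0.01, ellipses = FALSE, ...) {
  draw <- x$w_mean >= w_threshold
  xs <- c(x$G[, 1], if (any(draw)) x$Gstar[draw, 1])
  ys <- c(x$G[, 2], if (any(draw)) x$Gstar[draw, 2])
  plot.new()
  plot.window(range(xs) + c(-1, 1) * 0.05 * diff(range(xs)),
              range(ys) + c(-1, 1) * 0.05 * diff(range(ys)))
  axis(1); axis(2); box()
  title(xlab = "Eastings", ylab = "Northings")
  if (ellipses) {
    th <- seq(0, 2 * pi, length.out = 60)
    for (e in x$ellipses) {
      ev <- eigen(e$cov, symmetric = TRUE)
      lam <- sqrt(pmax(ev$values, 0)) * e$level_radius
      pts <- t(e$center + ev$vectors %*%
                 rbind(lam[1] * cos(th), lam[2] * sin(th)))
      polygon(pts, border = adjustcolor("grey50", 0.6), lty = 3)
    }
  }
  for (k in which(draw)) {
    arrows(x$Gstar[k, 1], x$Gstar[k, 2], x$G[k, 1], x$G[k, 2],
           length = 0.08, lwd = 0.5 + 6 * x$w_mean[k],
           col = adjustcolor("forestgreen", alpha.f = min(1, 0.2 + 1.6 * x$w_mean[k])))
  }
  text(x$G[, 1], x$G[, 2], labels = x$labels, cex = 0.7)
  invisible(x)
}

#' Write a geogenetic-map figure to file
#'
#' @param map a [summarize_map()] object.
#' @param output_path file path ending in .png, .pdf or .svg.
#' @param width,height device size in inches.
#' @param ... passed to [plot.geogenetic_map()].
#' @return `output_path`, invisibly.
#' @export
render_map <- function(map, output_path, width = 7, height = 7, ...) {
  ext <- tolower(tools::file_ext(output_path))
  opener <- switch(ext,
                   png = function() png(output_path, width = width,
                                        height = height, units = "in", res = 150),
                   pdf = function() pdf(output_path, width = width, height = height),
                   svg = function() svg(output_path, width = width, height = height),
                   stop("unsupported figure format: .", ext))
  opener()
  on.exit(dev.off())
  plot(map, ...)
  invisible(output_path)
}
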