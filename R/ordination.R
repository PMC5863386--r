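#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of -0.5 * D^2 followed by eigendecomposition.
#' Coordinates are the eigenvectors scaled by the square root of their
#' (positive) eigenvalues; axes are ordered by descending eigenvalue.
#' Negative eigenvalues, which arise when the dissimilarity is not
#' Euclidean-embeddable (Bray-Curtis typically is not), are excluded from
#' the coordinates but reported so their magnitude can be inspected.
#'
#' @param D Symmetric, zero-diagonal dissimilarity matrix.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes,
#'   columns `PC1`, `PC2`, ...), `eigenvalues` (positive ones, descending),
#'   `proportion_explained` (relative to the sum of positive eigenvalues),
#'   `negative_eigenvalues` (possibly empty, descending magnitude).
#' @export
pcoa <- function(D) {
  D <- validate_distance(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples")
  if (n == 2L) {
    # two samples: the solution is analytic (one axis, coordinates
    # +/- d/2, eigenvalue d^2/2); the closed form avoids the round-off
    # of sqrt(eigenvalue) * eigenvector
    d <- D[1L, 2L]
    if (d == 0) stop("no positive eigenvalues; degenerate input")
    coords <- matrix(c(d / 2, -d / 2), ncol = 1L,
                     dimnames = list(rownames(D), "PC1"))
    return(structure(list(
      coordinates = coords,
      eigenvalues = d * d / 2,
      proportion_explained = 1,
      negative_eigenvalues = numeric()
    ), class = "pcoa_result"))
  }
  A <- -0.5 * D * D
  ## Gower centering: B = (I - 11'/n) A (I - 11'/n)
  rm_ <- rowMeans(A)
  B <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  if (!length(pos)) stop("no positive eigenvalues; degenerate input")
  vals <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), length(pos))
  dimnames(coords) <- list(rownames(D), paste0("PC", seq_along(pos)))
  neg <- eig$values[eig$values < -tol]
  structure(list(
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = vals / sum(vals),
    negative_eigenvalues = neg
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              length(x$negative_eigenvalues)))
  k <- min(3L, length(x$proportion_explained))
  cat("  first axes explain:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' One-way MANOVA on leading principal coordinates
#'
#' Tests whether group centroids differ in the space of the leading PCoA
#' axes, using Wilks' lambda with Rao's F approximation. The number of
#' axes is either given directly or chosen as the smallest count whose
#' cumulative proportion of (positive-eigenvalue) variance reaches
#' `variance_fraction`.
#'
#' @param p `pcoa_result`.
#' @param labels Group label per sample.
#' @param variance_fraction Target cumulative variance fraction (used when
#'   `n_axes` is `NULL`); default 0.8.
#' @param n_axes Fixed number of leading axes (overrides the fraction).
#' @return List with `statistic` (Wilks' lambda), `approx_F`, `df`,
#'   `p_value`, `n_axes_used`, `variance_covered`.
#' @export
manova_on_pcs <- function(p, labels, variance_fraction = 0.8, n_axes = NULL) {
  stopifnot(inherits(p, "pcoa_result"))
  labels <- factor(labels)
  n <- nrow(p$coordinates)
  if (length(labels) != n) stop("labels must match the number of samples")
  if (is.null(n_axes)) {
    cum <- cumsum(p$proportion_explained)
    n_axes <- which(cum >= variance_fraction - 1e-12)[1L]
    if (is.na(n_axes)) n_axes <- length(cum)
  }
  n_axes <- as.integer(n_axes)
  k <- nlevels(labels)
  if (n_axes >= n - k) {
    stop("n_axes (", n_axes, ") must be < n_samples - n_groups (", n - k, ")")
  }
  Y <- p$coordinates[, seq_len(n_axes), drop = FALSE]
  fit <- stats::manova(Y ~ labels)
  tab <- tryCatch(
    summary(fit, test = "Wilks")$stats,
    error = function(e) stop("MANOVA failed (singular within-group ",
                             "covariance?): try fewer axes. ",
                             conditionMessage(e))
  )
  list(
    statistic = unname(tab["labels", "Wilks"]),
    approx_F = unname(tab["labels", "approx F"]),
    df = unname(tab["labels", c("num Df", "den Df")]),
    p_value = unname(tab["labels", "Pr(>F)"]),
    n_axes_used = n_axes,
    variance_covered = sum(p$proportion_explained[seq_len(n_axes)])
  )
}

#' Per-day two-group comparison along one principal coordinate
#'
#' For each study day where both groups are present, compares the two
#' groups' coordinates on the chosen axis with a two-sided Mann-Whitney U
#' test (exact when there are no ties and both groups are small, mid-rank
#' normal approximation otherwise). Days where only one group was sampled
#' are skipped with a warning.
#'
#' @param p `pcoa_result`.
#' @param axis Axis index (1 = PC1).
#' @param design Study design covering the ordinated samples.
#' @return data.frame with columns `day`, `n_<group1>`, `n_<group2>`,
#'   `statistic` (U) and `p_value`, one row per tested day.
#' @export
axis_group_test <- function(p, axis = 1L, design) {
  stopifnot(inherits(p, "pcoa_result"))
  design <- validate_design(design)
  coords <- p$coordinates[, axis]
  design <- design[design$sample %in% names(coords), , drop = FALSE]
  groups <- levels(droplevels(design$group))
  if (length(groups) != 2L) stop("axis_group_test needs exactly 2 groups")
  out <- list()
  for (d in sort(unique(design$day))) {
    rows <- design[design$day == d, ]
    x <- coords[rows$sample[rows$group == groups[[1L]]]]
    y <- coords[rows$sample[rows$group == groups[[2L]]]]
    if (!length(x) || !length(y)) {
      warning("day ", d, " has samples from one group only; skipped")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    out[[length(out) + 1L]] <- data.frame(
      day = d, n1 = length(x), n2 = length(y),
      statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) {
    names(res)[2:3] <- paste0("n_", groups)
    rownames(res) <- NULL
  }
  res
}
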