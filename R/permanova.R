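#' One-way PerMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' formulation. With N samples in k groups and d_ij the input
#' dissimilarities,
#' SS_total = (1/N) sum_{i<j} d_ij^2 and
#' SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2, giving
#' pseudo-F = ((SS_total - SS_within)/(k - 1)) / (SS_within/(N - k)).
#' Significance comes from permuting group labels: Monte-Carlo
#' p = (1 + #\{F* >= F_obs\}) / (1 + n_permutations), or in exhaustive mode
#' the exact proportion of all distinct label assignments (the observed one
#' included) with F* >= F_obs.
#'
#' @param D Symmetric, zero-diagonal dissimilarity matrix.
#' @param labels Group label per row of `D` (>= 2 groups, each >= 2 members).
#' @param n_permutations Number of Monte-Carlo permutations.
#' @param seed Integer seed for the permutations.
#' @param exhaustive If `TRUE`, enumerate every distinct assignment of the
#'   label multiset instead of sampling (only feasible for small N).
#' @return List of class `permanova_result` with `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations` (or assignments enumerated), `seed`,
#'   `exhaustive`, `df`.
#' @export
permanova <- function(D, labels, n_permutations = 9999L, seed = 1L,
                      exhaustive = FALSE) {
  D <- validate_distance(D)
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) stop("labels must match the matrix size")
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 members (no within-group df); offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  D2 <- D * D
  n <- nrow(D2)
  k <- length(sizes)
  ss_total <- sum(D2) / (2 * n)
  grp <- as.integer(factor(labels))
  f_obs <- pseudo_f(D2, grp, k, n, ss_total)
  tol <- 1e-10 * max(1, abs(f_obs))
  if (exhaustive) {
    perms <- enumerate_assignments(grp)
    f_star <- vapply(perms, function(g) pseudo_f(D2, g, k, n, ss_total),
                     numeric(1L))
    p <- sum(f_star >= f_obs - tol) / length(f_star)
    m <- length(f_star)
  } else {
    m <- as.integer(n_permutations)
    if (is.na(m) || m < 1L) stop("n_permutations must be >= 1")
    hits <- withr::with_seed(seed, {
      sum(vapply(seq_len(m), function(i) {
        pseudo_f(D2, grp[sample.int(n)], k, n, ss_total) >= f_obs - tol
      }, logical(1L)))
    })
    p <- (1 + hits) / (1 + m)
  }
  ss_within <- ss_within_groups(D2, grp, k)
  structure(list(
    pseudo_F = f_obs,
    R2 = 1 - ss_within / ss_total,
    p_value = p,
    n_permutations = m,
    seed = if (exhaustive) NA_integer_ else as.integer(seed),
    exhaustive = exhaustive,
    df = c(between = k - 1L, within = as.integer(n) - k)
  ), class = "permanova_result")
}

ss_within_groups <- function(D2, grp, k) {
  ss <- 0
  for (g in seq_len(k)) {
    idx <- grp == g
    ss <- ss + sum(D2[idx, idx]) / (2 * sum(idx))
  }
  ss
}

## pseudo-F from the squared-distance matrix and integer group codes
pseudo_f <- function(D2, grp, k, n, ss_total) {
  ss_within <- ss_within_groups(D2, grp, k)
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

## all distinct arrangements of a label multiset across positions
enumerate_assignments <- function(grp, max_assignments = 2e5) {
  n <- length(grp)
  counts <- tabulate(grp)
  total <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (total > max_assignments) {
    stop("exhaustive enumeration infeasible: ", format(total), " assignments")
  }
  recurse <- function(positions, remaining) {
    g <- which(remaining > 0)[1L]
    if (sum(remaining) == remaining[g]) {
      base <- integer(n)
      base[positions] <- g
      return(list(base))
    }
    rem <- remaining
    rem[g] <- 0L
    out <- list()
    for (combo in utils::combn(positions, remaining[g], simplify = FALSE)) {
      for (part in recurse(setdiff(positions, combo), rem)) {
        part[combo] <- g
        out[[length(out) + 1L]] <- part
      }
    }
    out
  }
  recurse(seq_len(n), counts)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PerMANOVA (one-way)\n")
  cat(sprintf("  pseudo-F = %.4f  R2 = %.4f  p = %.5g\n",
              x$pseudo_F, x$R2, x$p_value))
  cat(sprintf("  %s, %d %s\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations,
              if (x$exhaustive) "assignments" else "permutations"))
  invisible(x)
}

## symmetric zero-diagonal check shared by permanova/pcoa
validate_distance <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)
    stop("non-finite distances, e.g. between '",
         rownames(D)[bad[1, 1]], "' and '", colnames(D)[bad[1, 2]], "'")
  }
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have a zero diagonal")
  D
}
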