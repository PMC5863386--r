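#' Observed OTU richness of one sample
#'
#' @param x Non-negative count (or abundance) vector.
#' @return Number of strictly positive entries.
#' @export
observed_otus <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  sum(x > 0)
}

#' Shannon diversity index (base 2) of one sample
#'
#' H = -sum p_i log2 p_i over the positive entries, with p_i the
#' within-sample proportions.
#'
#' @param x Non-negative vector with positive total.
#' @return Shannon index in bits.
#' @export
shannon <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  total <- sum(x)
  if (total <= 0) stop("Shannon index undefined for an all-zero sample")
  p <- x[x > 0] / total
  -sum(p * log2(p))
}

#' Alpha diversity averaged over repeated rarefactions
#'
#' Rarefies the table `n_reps` times with independent sub-seeds and
#' averages observed OTUs and the Shannon index per sample, the classic
#' multiple-rarefaction protocol that removes the sampling noise of any
#' single subsample. Samples below `depth` are excluded (reported via the
#' `dropped_samples` attribute).
#'
#' @param counts Samples x OTUs integer matrix.
#' @param depth Rarefaction depth.
#' @param n_reps Number of independent rarefactions to average (>= 1).
#' @param seed Integer seed for the whole procedure.
#' @return data.frame with one row per retained sample: `sample`,
#'   `observed_otus`, `shannon` (replicate means), `observed_otus_sd`,
#'   `shannon_sd`, `n_replicates`, `depth`; attribute `dropped_samples`.
#' @export
alpha_over_rarefactions <- function(counts, depth = 8000L, n_reps = 1000L,
                                    seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  obs <- sh <- NULL
  dropped <- character()
  for (r in seq_len(n_reps)) {
    rar <- rarefy(counts, depth, seed = sub_seeds[[r]])
    if (r == 1L) {
      dropped <- attr(rar, "dropped_samples")
      obs <- sh <- matrix(NA_real_, nrow = nrow(rar), ncol = n_reps,
                          dimnames = list(rownames(rar), NULL))
    }
    obs[, r] <- rowSums(rar > 0)
    sh[, r] <- apply(rar, 1L, shannon)
  }
  out <- data.frame(
    sample = rownames(obs),
    observed_otus = rowMeans(obs),
    shannon = rowMeans(sh),
    observed_otus_sd = apply(obs, 1L, stats::sd),
    shannon_sd = apply(sh, 1L, stats::sd),
    n_replicates = n_reps,
    depth = depth,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped_samples") <- dropped
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed between all
#' sample pairs. Scale-invariant under common rescaling, so it gives the
#' same answer on equal-depth counts and on relative abundances.
#'
#' @param ab Samples x OTUs abundance (or equal-depth count) matrix with
#'   at least two samples.
#' @return Symmetric matrix of dissimilarities in \[0, 1\] with a zero
#'   diagonal and sample IDs as dimnames.
#' @export
bray_curtis_matrix <- function(ab) {
  if (!is.matrix(ab) || nrow(ab) < 2L) stop("need a matrix with >= 2 samples")
  zero <- rowSums(ab) == 0
  if (sum(zero) >= 2L) {
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(rownames(ab)[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(ab, method = "bray"))
  dimnames(d) <- list(rownames(ab), rownames(ab))
  d
}
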