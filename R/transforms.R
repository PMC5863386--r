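#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth`. Samples whose total is below `depth`
#' cannot be rarefied and are dropped; their IDs are recorded in the
#' `"dropped_samples"` attribute of the result so callers can log them
#' rather than fail.
#'
#' @param counts Samples x OTUs integer matrix.
#' @param depth Target depth (reads per sample), `>= 1`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Rarefied integer matrix (retained samples x OTUs), every row
#'   summing to `depth`, with attribute `dropped_samples` (character vector
#'   of excluded sample IDs, possibly empty).
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  validate_otu_table(counts)
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0L) stop("depth must be a positive integer")
  totals <- rowSums(counts)
  keep <- totals >= depth
  dropped <- rownames(counts)[!keep]
  if (!any(keep)) stop("no sample reaches depth ", depth)
  sub <- counts[keep, , drop = FALSE]
  out <- withr::with_seed(seed, {
    t(apply(sub, 1L, subsample_vector, depth = depth))
  })
  dimnames(out) <- dimnames(sub)
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- dropped
  out
}

## draw `depth` reads without replacement from a count vector
subsample_vector <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(as.integer(x))
  pos <- sample.int(total, depth)      # which reads survive
  cum <- cumsum(x)
  tabulate(findInterval(pos - 1L, cum) + 1L, nbins = length(x))
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample's counts are divided by its total. All-zero samples cannot
#' be normalized; they are kept (as all-zero rows) and flagged in the
#' `"empty_samples"` attribute instead of producing NaN.
#'
#' @param counts Samples x OTUs matrix of non-negative counts.
#' @param provenance Free-form string recording how the counts were made
#'   (e.g. `"raw"` or `"rarefied:8000:42"`), stored as an attribute.
#' @return Numeric matrix of proportions with attributes `empty_samples`
#'   and `provenance`. Non-empty rows sum to 1.
#' @export
relative_abundance <- function(counts, provenance = "raw") {
  validate_otu_table(counts)
  totals <- rowSums(counts)
  empty <- totals == 0
  totals[empty] <- 1  # leave empty rows at zero rather than divide by 0
  ab <- counts / totals
  attr(ab, "empty_samples") <- rownames(counts)[empty]
  attr(ab, "provenance") <- provenance
  ab
}
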