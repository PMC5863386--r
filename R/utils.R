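#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between a recovered clustering and a
#' reference partition (1 = identical up to relabeling, ~0 = random).
#' Used to score planted-CAG recovery against simulator truth.
#'
#' @param a,b Cluster labels over the same items (any atomic type).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
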