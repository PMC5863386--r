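#' Cluster OTUs into co-abundance groups by sequential PerMANOVA tree-cut
#'
#' Converts the within-subject correlation matrix to a correlation distance
#' (1 - r), builds a Ward dendrogram (Ward.D2 criterion), then walks the
#' tree from the top: at each internal node a one-way PerMANOVA is run on
#' the node's OTU-by-OTU distance sub-matrix with the two child clades as
#' groups. If the clades differ significantly (p < `alpha`) and both hold
#' at least `min_clade` OTUs, the split is accepted and both children are
#' visited; otherwise the node's leaves become one co-abundance group
#' (CAG). CAGs are numbered in leaf order of the dendrogram.
#'
#' Undefined correlations (from zero-variance OTUs) are imputed as r = 0
#' for the clustering and flagged, so the partition always covers every
#' OTU.
#'
#' @param C Correlation matrix (e.g. from [repeated_corr()]).
#' @param alpha Split acceptance level (default 0.001).
#' @param n_permutations PerMANOVA permutations per node (default 9999).
#' @param min_clade Smallest clade size an accepted split may produce
#'   (default 3, so each PerMANOVA group has within-group df).
#' @param seed Integer seed for the node tests.
#' @return List of class `cag_assignment`: `assignment` (named integer
#'   vector otu -> CAG id), `dendrogram` (`hclust`), `splits` (data.frame
#'   of every node tested: sizes, pseudo-F, p, accepted), `alpha`,
#'   `min_clade`, `n_permutations`, `seed`, `imputed_otus`.
#' @export
build_cags <- function(C, alpha = 0.001, n_permutations = 9999L,
                       min_clade = 3L, seed = 1L) {
  r <- unclass(C)
  if (!is.matrix(r) || nrow(r) != ncol(r) || nrow(r) < 2L) {
    stop("need a square correlation matrix with >= 2 OTUs")
  }
  otus <- rownames(r)
  imputed <- attr(C, "undefined_otus")
  if (is.null(imputed)) imputed <- character()
  na_off <- is.na(r)
  diag(na_off) <- FALSE
  if (any(na_off)) {
    flagged <- otus %in% imputed
    explained <- outer(flagged, flagged, "|")
    if (any(na_off & !explained)) {
      bad <- which(na_off & !explained, arr.ind = TRUE)[1L, ]
      stop("non-finite correlation between '", otus[bad[[1L]]], "' and '",
           otus[bad[[2L]]], "' with no zero-variance flag")
    }
    r[na_off] <- 0
    imputed <- otus[flagged & apply(na_off, 1L, any)]
  }
  d <- 1 - r
  d <- (d + t(d)) / 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")

  n <- nrow(d)
  leaves_of <- node_leaf_sets(hc$merge, n)
  node_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max, n - 1L))
  assignment <- integer(n)
  names(assignment) <- otus
  splits <- list()
  next_cag <- 0L

  assign_clade <- function(node) {
    ## node > 0: internal node index into merge; node < 0: leaf
    if (node < 0L) {
      next_cag <<- next_cag + 1L
      assignment[-node] <<- next_cag
      return(invisible())
    }
    kids <- hc$merge[node, ]
    left <- if (kids[[1L]] < 0L) -kids[[1L]] else leaves_of[[kids[[1L]]]]
    right <- if (kids[[2L]] < 0L) -kids[[2L]] else leaves_of[[kids[[2L]]]]
    testable <- length(left) >= min_clade && length(right) >= min_clade
    p <- NA_real_
    f <- NA_real_
    if (testable) {
      idx <- c(left, right)
      lab <- rep(c("L", "R"), c(length(left), length(right)))
      pr <- permanova(d[idx, idx, drop = FALSE], lab,
                      n_permutations = n_permutations,
                      seed = node_seeds[[node]])
      p <- pr$p_value
      f <- pr$pseudo_F
    }
    accepted <- testable && p < alpha
    splits[[length(splits) + 1L]] <<- data.frame(
      node = node, n_left = length(left), n_right = length(right),
      pseudo_F = f, p_value = p, accepted = accepted)
    if (accepted) {
      assign_clade(kids[[1L]])
      assign_clade(kids[[2L]])
    } else {
      next_cag <<- next_cag + 1L
      assignment[c(left, right)] <<- next_cag
    }
    invisible()
  }
  assign_clade(n - 1L)  # root

  ## renumber CAGs in dendrogram leaf order for stable, readable ids
  first_leaf <- tapply(match(seq_len(n), hc$order), assignment, min)
  relabel <- rank(first_leaf)
  assignment <- as.integer(relabel[as.character(assignment)])
  names(assignment) <- otus

  structure(list(
    assignment = assignment,
    dendrogram = hc,
    splits = do.call(rbind, splits),
    alpha = alpha,
    min_clade = as.integer(min_clade),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    imputed_otus = imputed
  ), class = "cag_assignment")
}

## leaf index sets for every internal node of an hclust merge matrix
node_leaf_sets <- function(merge, n) {
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    l <- merge[i, 1L]
    r <- merge[i, 2L]
    sets[[i]] <- c(if (l < 0L) -l else sets[[l]],
                   if (r < 0L) -r else sets[[r]])
  }
  sets
}

#' @export
print.cag_assignment <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("%d OTUs in %d co-abundance groups (alpha = %g)\n",
              length(x$assignment), length(sizes), x$alpha))
  cat("  CAG sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Export the co-abundance network as a GraphML graph
#'
#' Nodes are OTUs, attributed with their CAG id and phylum; an undirected
#' edge connects every OTU pair whose correlation magnitude exceeds
#' `r_threshold` (strictly), carrying the signed correlation as weight.
#' The GraphML file imports directly into Cytoscape.
#'
#' @param C Correlation matrix.
#' @param cags `cag_assignment` over the same OTUs.
#' @param taxonomy Taxonomy data.frame (`otu`, `lineage`, `confidence`);
#'   OTUs missing from it get phylum `"unassigned"`.
#' @param r_threshold Edge threshold on |r| (default 0.5, strict).
#' @param path Optional output path; when given the GraphML file is
#'   written there.
#' @return An `igraph` graph, invisibly if `path` is given.
#' @export
build_network <- function(C, cags, taxonomy = NULL, r_threshold = 0.5,
                          path = NULL) {
  r <- unclass(C)
  otus <- rownames(r)
  stopifnot(inherits(cags, "cag_assignment"))
  phylum <- rep("unassigned", length(otus))
  if (!is.null(taxonomy)) {
    m <- match(otus, taxonomy$otu)
    hit <- !is.na(m)
    phylum[hit] <- lineage_rank(taxonomy$lineage[m[hit]], 2L)
  }
  g <- igraph::make_empty_graph(n = length(otus), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = otus)
  g <- igraph::set_vertex_attr(g, "cag", value = paste0(
    "CAG", cags$assignment[otus]))
  g <- igraph::set_vertex_attr(g, "phylum", value = phylum)
  ut <- upper.tri(r)
  hits <- which(ut & !is.na(r) & abs(r) > r_threshold, arr.ind = TRUE)
  if (nrow(hits)) {
    g <- igraph::add_edges(g, rbind(hits[, 1L], hits[, 2L]),
                           weight = r[hits],
                           sign = ifelse(r[hits] > 0, "positive", "negative"))
  }
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}

#' Per-sample and per-day CAG abundance series
#'
#' For every sample, sums the relative abundances of each CAG's member
#' OTUs; then summarizes per group and day as mean and standard error over
#' subjects. Because CAGs partition the clustered OTUs, the per-sample CAG
#' totals never exceed 1.
#'
#' @param ab Samples x OTUs relative-abundance matrix (must contain every
#'   clustered OTU).
#' @param design Study design covering the samples.
#' @param cags `cag_assignment`.
#' @return List of class `cag_dynamics`: `per_sample` (long data.frame
#'   `sample`, `subject`, `group`, `day`, `cag`, `abundance`) and
#'   `by_day` (`group`, `day`, `cag`, `mean`, `sem`, `n`).
#' @export
cag_series <- function(ab, design, cags) {
  stopifnot(inherits(cags, "cag_assignment"))
  design <- validate_design(design)
  otus <- names(cags$assignment)
  missing_otus <- setdiff(otus, colnames(ab))
  if (length(missing_otus)) {
    stop("abundance table lacks clustered OTUs: ",
         paste(missing_otus, collapse = ", "))
  }
  design <- design[design$sample %in% rownames(ab), , drop = FALSE]
  X <- ab[design$sample, otus, drop = FALSE]
  cag_f <- factor(paste0("CAG", cags$assignment),
                  levels = paste0("CAG", sort(unique(cags$assignment))))
  totals <- t(rowsum(t(X), cag_f))  # samples x CAGs
  per_sample <- data.frame(
    sample = rep(design$sample, ncol(totals)),
    subject = rep(design$subject, ncol(totals)),
    group = rep(as.character(design$group), ncol(totals)),
    day = rep(design$day, ncol(totals)),
    cag = rep(colnames(totals), each = nrow(totals)),
    abundance = as.vector(totals),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(abundance ~ group + day + cag, data = per_sample,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v)),
                                              n = length(v)))
  by_day <- data.frame(agg[, c("group", "day", "cag")],
                       mean = agg$abundance[, "mean"],
                       sem = agg$abundance[, "sem"],
                       n = as.integer(agg$abundance[, "n"]),
                       stringsAsFactors = FALSE)
  by_day <- by_day[order(by_day$cag, by_day$group, by_day$day), ]
  rownames(by_day) <- NULL
  structure(list(per_sample = per_sample, by_day = by_day),
            class = "cag_dynamics")
}

#' Onset day of a CAG's change from baseline
#'
#' The day a CAG "begins to change": the smallest day d > 0 whose group
#' mean abundance m_d satisfies |log2((m_d + epsilon) / (m_0 + epsilon))| >
#' 1 (strictly), with m_0 the day-0 mean and epsilon a pseudocount that
#' keeps the ratio finite for empty baselines.
#'
#' @param dynamics `cag_dynamics`.
#' @param cag_id CAG label (e.g. `"CAG1"`) or integer id.
#' @param group Group whose series is scanned.
#' @param epsilon Pseudocount (default 1e-6).
#' @return Integer onset day, or `NA` if the rule never triggers.
#' @export
onset_day <- function(dynamics, cag_id, group, epsilon = 1e-6) {
  stopifnot(inherits(dynamics, "cag_dynamics"))
  if (is.numeric(cag_id)) cag_id <- paste0("CAG", cag_id)
  s <- dynamics$by_day
  s <- s[s$cag == cag_id & s$group == group, , drop = FALSE]
  if (!nrow(s)) stop("no series for ", cag_id, " in group ", group)
  if (!any(s$day == 0L)) stop("day 0 (baseline) missing from the series")
  m0 <- s$mean[s$day == 0L]
  s <- s[order(s$day), ]
  lfc <- log2((s$mean + epsilon) / (m0 + epsilon))
  hit <- which(s$day > 0L & abs(lfc) > 1)
  if (!length(hit)) NA_integer_ else as.integer(s$day[hit[[1L]]])
}

#' Kruskal-Wallis omnibus and Dunn baseline comparisons for one CAG
#'
#' Tests whether a CAG's per-subject abundances differ across study days
#' within one group: an omnibus Kruskal-Wallis test over all days,
#' followed by Dunn's rank-based z comparisons of every later day against
#' day 0, with the p-values adjusted over that day-vs-baseline family
#' (Bonferroni by default).
#'
#' @param dynamics `cag_dynamics`.
#' @param cag_id CAG label or integer id.
#' @param group Group whose series is tested.
#' @param p_adjust Adjustment method over the baseline family (any
#'   [stats::p.adjust()] method; default `"bonferroni"`).
#' @return List with `kruskal` (`statistic`, `df`, `p_value`) and
#'   `vs_baseline` (data.frame `day`, `z`, `p_value`, `p_adjusted`).
#' @export
kw_dunn_vs_baseline <- function(dynamics, cag_id, group,
                                p_adjust = "bonferroni") {
  stopifnot(inherits(dynamics, "cag_dynamics"))
  if (is.numeric(cag_id)) cag_id <- paste0("CAG", cag_id)
  s <- dynamics$per_sample
  s <- s[s$cag == cag_id & s$group == group, , drop = FALSE]
  if (!nrow(s)) stop("no series for ", cag_id, " in group ", group)
  if (!any(s$day == 0L)) stop("day 0 (baseline) missing")
  days <- factor(s$day)
  counts <- table(days)
  if (sum(counts >= 2L) < 2L) stop("need >= 2 days with >= 2 subjects each")
  if (length(unique(s$abundance)) == 1L) {
    return(list(kruskal = list(statistic = 0, df = nlevels(days) - 1L,
                               p_value = 1),
                vs_baseline = NULL))
  }
  kw <- stats::kruskal.test(s$abundance, days)
  vs <- dunn_vs_baseline(s$abundance, days, baseline = "0",
                         p_adjust = p_adjust)
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = kw$p.value),
       vs_baseline = vs)
}

## Dunn's test of each level vs the baseline level, on pooled mid-ranks
## with tie correction; two-sided normal p-values.
dunn_vs_baseline <- function(values, groups, baseline, p_adjust) {
  groups <- factor(groups)
  rk <- rank(values)
  N <- length(values)
  mean_rank <- tapply(rk, groups, mean)
  n <- table(groups)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  variance_unit <- N * (N + 1) / 12 - tie_corr
  others <- setdiff(levels(groups), baseline)
  z <- (mean_rank[others] - mean_rank[[baseline]]) /
    sqrt(variance_unit * (1 / n[others] + 1 / n[[baseline]]))
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(day = as.integer(others), z = as.numeric(z),
                    p_value = as.numeric(p),
                    p_adjusted = stats::p.adjust(as.numeric(p),
                                                 method = p_adjust),
                    stringsAsFactors = FALSE)
  out[order(out$day), , drop = FALSE]
}
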