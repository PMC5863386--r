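# symmetric correlation matrix with planted blocks
planted_corr <- function(sizes, within = 0.8, between = -0.1, noise = 0.02,
                         seed = 1) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    jit <- matrix(runif(n * n, -noise, noise), n, n)
  })
  jit <- (jit + t(jit)) / 2
  r <- ifelse(outer(block, block, "=="), within, between) + jit
  diag(r) <- 1
  dimnames(r) <- list(paste0("o", seq_len(n)), paste0("o", seq_len(n)))
  r
}

# minimal assignment object for functions that only read $assignment
fake_cags <- function(assignment) {
  structure(list(assignment = assignment), class = "cag_assignment")
}

test_that("tree-cut recovers planted correlation blocks exactly", {
  r <- planted_corr(c(6, 6, 6))
  cags <- build_cags(r, alpha = 0.01, n_permutations = 9999, seed = 3)
  truth <- rep(1:3, each = 6)
  expect_equal(adjusted_rand_index(cags$assignment, truth), 1)
  expect_equal(length(unique(cags$assignment)), 3L)
  # every accepted split was significant at alpha, rejected ones were not
  acc <- cags$splits[cags$splits$accepted, ]
  expect_true(all(acc$p_value < cags$alpha))
  expect_true(all(acc$n_left >= cags$min_clade & acc$n_right >= cags$min_clade))
  # CAG ids follow dendrogram leaf order
  leaf_cags <- cags$assignment[cags$dendrogram$order]
  expect_equal(unique(leaf_cags), sort(unique(leaf_cags)))
})

test_that("featureless correlation yields a single CAG", {
  n <- 8
  r <- matrix(0.4, n, n, dimnames = list(paste0("o", 1:n), paste0("o", 1:n)))
  diag(r) <- 1
  cags <- build_cags(r, alpha = 0.01, n_permutations = 99, seed = 1)
  expect_equal(unname(unique(cags$assignment)), 1L)
  expect_false(any(cags$splits$accepted))
})

test_that("splits below min_clade are never tested or accepted", {
  r <- planted_corr(c(2, 6))
  cags <- build_cags(r, alpha = 0.05, n_permutations = 999, min_clade = 3,
                     seed = 2)
  # the only natural split would isolate 2 < min_clade OTUs
  expect_equal(unname(unique(cags$assignment)), 1L)
  root <- cags$splits[cags$splits$node == nrow(r) - 1L, ]
  expect_true(is.na(root$p_value))
  expect_false(root$accepted)
})

test_that("partition is invariant to OTU ordering (up to relabeling)", {
  r <- planted_corr(c(6, 6))
  withr::with_seed(7, {
    perm <- sample(nrow(r))
  })
  a <- build_cags(r, alpha = 0.01, n_permutations = 9999, seed = 5)
  b <- build_cags(r[perm, perm], alpha = 0.01, n_permutations = 9999, seed = 5)
  common <- rownames(r)
  expect_equal(adjusted_rand_index(a$assignment[common],
                                   b$assignment[common]), 1)
})

test_that("zero-variance OTUs are imputed, flagged and still assigned", {
  r <- planted_corr(c(6, 6))
  r["o3", -3] <- NA
  r[-3, "o3"] <- NA
  attr(r, "undefined_otus") <- "o3"
  cags <- build_cags(r, alpha = 0.01, n_permutations = 9999, seed = 4)
  expect_identical(cags$imputed_otus, "o3")
  expect_true("o3" %in% names(cags$assignment))

  # an unexplained NA is an error
  r2 <- planted_corr(c(4, 4))
  r2["o1", "o2"] <- NA
  r2["o2", "o1"] <- NA
  expect_error(build_cags(r2, n_permutations = 99), "zero-variance")
})

test_that("network edges reproduce a brute-force threshold scan", {
  r <- planted_corr(c(5, 5), within = 0.7, between = -0.6, noise = 0.1,
                    seed = 9)
  cags <- fake_cags(stats::setNames(rep(1:2, each = 5), rownames(r)))
  tax <- data.frame(otu = rownames(r),
                    lineage = rep(c("Bacteria;Firmicutes;Bacilli",
                                    "Bacteria;Bacteroidetes"), 5),
                    confidence = 1, stringsAsFactors = FALSE)
  g <- build_network(r, cags, tax, r_threshold = 0.5)
  want <- which(upper.tri(r) & abs(r) > 0.5, arr.ind = TRUE)
  expect_equal(igraph::ecount(g), nrow(want))
  el <- igraph::as_edgelist(g)
  got <- sort(paste(el[, 1], el[, 2]))
  expect_equal(got, sort(paste(rownames(r)[want[, 1]],
                               rownames(r)[want[, 2]])))
  expect_equal(sort(unique(igraph::vertex_attr(g, "phylum"))),
               c("Bacteroidetes", "Firmicutes"))
  expect_equal(igraph::vertex_attr(g, "cag", "o1"), "CAG1")
  w <- igraph::edge_attr(g, "weight")
  expect_equal(igraph::edge_attr(g, "sign"),
               ifelse(w > 0, "positive", "negative"))
})

test_that("the edge threshold is strict: |r| equal to it draws no edge", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  g <- build_network(r, fake_cags(c(a = 1L, b = 1L)), r_threshold = 0.5)
  expect_equal(igraph::ecount(g), 0)
  g2 <- build_network(r, fake_cags(c(a = 1L, b = 1L)), r_threshold = 0.499)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("GraphML export round-trips node and edge attributes", {
  r <- planted_corr(c(4, 4), within = 0.9, between = -0.7)
  cags <- fake_cags(stats::setNames(rep(1:2, each = 4), rownames(r)))
  path <- withr::local_tempfile(fileext = ".graphml")
  build_network(r, cags, r_threshold = 0.5, path = path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 8)
  expect_equal(sort(igraph::vertex_attr(back, "name")), sort(rownames(r)))
  expect_true(all(abs(igraph::edge_attr(back, "weight")) > 0.5))
})

test_that("CAG series sums member abundances and partitions each sample", {
  des <- rbind(toy_design(paste0("c", 1:3), c(0, 7), group = "CR"))
  withr::with_seed(6, {
    ab <- matrix(runif(nrow(des) * 6), ncol = 6,
                 dimnames = list(des$sample, paste0("o", 1:6)))
  })
  ab <- ab / rowSums(ab)
  cags <- fake_cags(stats::setNames(rep(1:2, each = 3), paste0("o", 1:6)))
  dyn <- cag_series(ab, des, cags)
  ps <- dyn$per_sample
  # hand check one cell
  expect_equal(ps$abundance[ps$sample == "c1_d0" & ps$cag == "CAG1"],
               sum(ab["c1_d0", 1:3]))
  # partition: CAG totals sum to the row totals (= 1)
  sums <- tapply(ps$abundance, ps$sample, sum)
  expect_equal(as.vector(sums), rep(1, nrow(ab)), tolerance = 1e-12)
  # by_day mean/sem over the three subjects
  v <- ps$abundance[ps$cag == "CAG2" & ps$day == 7]
  row <- dyn$by_day[dyn$by_day$cag == "CAG2" & dyn$by_day$day == 7, ]
  expect_equal(row$mean, mean(v))
  expect_equal(row$sem, sd(v) / sqrt(3))
  expect_equal(row$n, 3L)
})

# hand-built dynamics with one CAG and chosen group means
dynamics_from_means <- function(means_by_day, group = "CR", n_per = 4) {
  days <- as.integer(names(means_by_day))
  per <- do.call(rbind, lapply(seq_along(days), function(i) {
    data.frame(sample = paste0("m", 1:n_per, "_d", days[i]),
               subject = paste0("m", 1:n_per), group = group, day = days[i],
               cag = "CAG1", abundance = means_by_day[[i]],
               stringsAsFactors = FALSE)
  }))
  by_day <- data.frame(group = group, day = days, cag = "CAG1",
                       mean = unname(means_by_day), sem = 0,
                       n = n_per, stringsAsFactors = FALSE)
  structure(list(per_sample = per, by_day = by_day), class = "cag_dynamics")
}

test_that("onset day triggers strictly past a twofold change", {
  d <- dynamics_from_means(c("0" = 0.10, "3" = 0.20, "7" = 0.21, "14" = 0.50))
  # day 3 is exactly 2x: |log2 fc| = 1 is NOT > 1, so onset is day 7
  expect_equal(onset_day(d, "CAG1", "CR", epsilon = 0), 7L)

  d2 <- dynamics_from_means(c("0" = 0.4, "3" = 0.3, "7" = 0.09))
  expect_equal(onset_day(d2, 1, "CR"), 7L)  # depletion side, integer id

  d3 <- dynamics_from_means(c("0" = 0.2, "3" = 0.25, "7" = 0.3))
  expect_true(is.na(onset_day(d3, "CAG1", "CR")))

  # empty baseline: epsilon keeps the ratio finite and the rule fires
  d4 <- dynamics_from_means(c("0" = 0, "3" = 0.1))
  expect_equal(onset_day(d4, "CAG1", "CR", epsilon = 1e-6), 3L)

  expect_error(onset_day(d, "CAG9", "CR"), "no series")
  expect_error(onset_day(dynamics_from_means(c("3" = 1, "7" = 2)),
                         "CAG1", "CR"), "baseline")
})

test_that("Kruskal-Wallis and Dunn match hand-computed rank statistics", {
  # two days, values {1,2,3} vs {4,5,6}: mean ranks 2 and 5,
  # H = 12/(6*7) * 3*((2-3.5)^2 + (5-3.5)^2) = 27/7
  per <- data.frame(sample = paste0("s", 1:6),
                    subject = paste0("m", c(1:3, 1:3)),
                    group = "CR", day = rep(c(0L, 7L), each = 3),
                    cag = "CAG1", abundance = 1:6, stringsAsFactors = FALSE)
  dyn <- structure(list(per_sample = per, by_day = NULL),
                   class = "cag_dynamics")
  res <- kw_dunn_vs_baseline(dyn, "CAG1", "CR")
  expect_equal(res$kruskal$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(res$kruskal$df, 1L)
  expect_equal(res$kruskal$p_value,
               stats::kruskal.test(1:6, rep(c(0, 7), each = 3))$p.value)
  # Dunn z: (5 - 2) / sqrt((6*7/12) * (1/3 + 1/3)) = 3 / sqrt(7/3)
  expect_equal(res$vs_baseline$z, 3 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(res$vs_baseline$p_value,
               2 * stats::pnorm(-3 / sqrt(7 / 3)), tolerance = 1e-12)
  expect_equal(res$vs_baseline$p_adjusted, res$vs_baseline$p_value)
})

test_that("Dunn adjusts over the day family and handles all-tied data", {
  per <- data.frame(sample = paste0("s", 1:12),
                    subject = paste0("m", rep(1:4, 3)),
                    group = "CR", day = rep(c(0L, 7L, 14L), each = 4),
                    cag = "CAG1",
                    abundance = c(1, 2, 3, 4, 9, 10, 11, 12, 5, 6, 7, 8),
                    stringsAsFactors = FALSE)
  dyn <- structure(list(per_sample = per, by_day = NULL),
                   class = "cag_dynamics")
  res <- kw_dunn_vs_baseline(dyn, "CAG1", "CR", p_adjust = "bonferroni")
  expect_equal(nrow(res$vs_baseline), 2L)
  expect_equal(res$vs_baseline$p_adjusted,
               pmin(1, res$vs_baseline$p_value * 2))

  per$abundance <- 5
  tied <- kw_dunn_vs_baseline(structure(list(per_sample = per, by_day = NULL),
                                        class = "cag_dynamics"), "CAG1", "CR")
  expect_equal(tied$kruskal$p_value, 1)
  expect_null(tied$vs_baseline)
})

test_that("planted abundance shifts produce significant baseline contrasts", {
  withr::with_seed(12, {
    base <- runif(8, 0.1, 0.12)
  })
  per <- do.call(rbind, lapply(c(0L, 7L, 14L), function(d) {
    lift <- if (d == 14L) 0.3 else 0
    data.frame(sample = paste0("m", 1:8, "_d", d), subject = paste0("m", 1:8),
               group = "CR", day = d, cag = "CAG1",
               abundance = base + lift, stringsAsFactors = FALSE)
  }))
  dyn <- structure(list(per_sample = per, by_day = NULL),
                   class = "cag_dynamics")
  res <- kw_dunn_vs_baseline(dyn, "CAG1", "CR")
  vs <- res$vs_baseline
  expect_lt(vs$p_adjusted[vs$day == 14], 0.01)
  expect_gt(vs$p_adjusted[vs$day == 7], 0.5)
})
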