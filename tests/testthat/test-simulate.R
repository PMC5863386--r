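test_that("simulation is fully reproducible from its seed", {
  cfg <- small_sim_config(seed = 4)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$design, b$design)
  c2 <- simulate_study(small_sim_config(seed = 5))
  expect_false(identical(a$counts, c2$counts))
})

test_that("design, dimensions and truth labels are internally consistent", {
  cfg <- small_sim_config()
  sim <- simulate_study(cfg)
  n_samples <- 2 * cfg$n_subjects_per_group * length(cfg$days)
  expect_equal(dim(sim$counts), c(n_samples, cfg$n_otus))
  expect_identical(rownames(sim$counts), sim$design$sample)
  expect_type(sim$counts[1, 1], "integer")
  expect_true(all(sim$counts >= 0))

  tr <- sim$truth$otu
  expect_equal(nrow(tr), cfg$n_otus)
  expect_equal(sum(!is.na(tr$cag)), sum(cfg$cag_sizes))
  expect_equal(as.vector(table(tr$cag)), cfg$cag_sizes)
  # differential = member of a dynamic CAG or a standalone trajectory OTU
  expect_equal(sum(tr$differential), sum(cfg$cag_sizes[cfg$cag_log2fc != 0]) +
                 cfg$n_extra_differential)
  expect_equal(sim$truth$cag$log2fc, cfg$cag_log2fc)
})

test_that("read depths follow the log-normal depth model", {
  cfg <- small_sim_config()
  sim <- simulate_study(cfg)
  depths <- rowSums(sim$counts)
  expect_true(all(depths >= 1))
  # within generous log-normal quantiles of the configured distribution
  lo <- qlnorm(1e-5, cfg$depth_meanlog, cfg$depth_sdlog)
  hi <- qlnorm(1 - 1e-5, cfg$depth_meanlog, cfg$depth_sdlog)
  expect_true(all(depths > lo & depths < hi))
})

test_that("planted trajectories move treated-group abundances as configured", {
  cfg <- small_sim_config(seed = 2)  # CAG1 +3, CAG2 static, CAG3 -3
  sim <- simulate_study(cfg)
  ab <- relative_abundance(sim$counts)
  d <- sim$design
  last <- max(cfg$days)
  mean_cag <- function(group, day, cag) {
    otus <- sim$truth$otu$otu[!is.na(sim$truth$otu$cag) &
                                sim$truth$otu$cag == cag]
    mean(rowSums(ab[d$sample[d$group == group & d$day == day], otus]))
  }
  # enriched CAG rises in CR, depleted falls, relative to NC at endpoint
  expect_gt(mean_cag("CR", last, "CAG1") / mean_cag("NC", last, "CAG1"), 2)
  expect_lt(mean_cag("CR", last, "CAG3") / mean_cag("NC", last, "CAG3"), 0.5)
  # at baseline the groups are exchangeable: ratios near 1
  expect_lt(abs(log2(mean_cag("CR", 0, "CAG1") / mean_cag("NC", 0, "CAG1"))), 1)
})

test_that("CAG members co-vary more within than between CAGs", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_study(cfg)
  ab <- relative_abundance(sim$counts)
  C <- repeated_corr(ab, sim$design,
                     otus = sim$truth$otu$otu[!is.na(sim$truth$otu$cag)],
                     window_days = c(0, max(cfg$days)))
  r <- unclass(C)
  blk <- rep(1:3, each = 8)
  same <- outer(blk, blk, "==") & upper.tri(r)
  diff <- !outer(blk, blk, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]) + 0.2)
})

test_that("larger theta reduces count overdispersion", {
  disp <- sapply(c(20, 2000), function(th) {
    cfg <- sim_config(n_subjects_per_group = 6L, days = 0L, n_otus = 40L,
                      cag_sizes = 4L, cag_log2fc = 0, cag_ramp_start = 0L,
                      n_extra_differential = 0L, extra_diff_log2fc = numeric(),
                      extra_diff_ramp_start = integer(), ramp_end_day = 5L,
                      subject_sd = 0, cag_factor_sd = 0, otu_noise_sd = 0,
                      theta = th, depth_meanlog = log(5000), depth_sdlog = 0,
                      seed = 11L)
    sim <- simulate_study(cfg)
    ab <- relative_abundance(sim$counts)
    # with all latent noise off, between-sample spread is purely sampling +
    # Dirichlet overdispersion
    mean(apply(ab, 2, sd))
  })
  expect_gt(disp[1], 2 * disp[2])
})

test_that("taxonomy covers every OTU and pins the dominant CAG's genus", {
  sim <- simulate_study(small_sim_config())
  expect_identical(sim$taxonomy$otu, colnames(sim$counts))
  cag1 <- sim$truth$otu$otu[!is.na(sim$truth$otu$cag) &
                              sim$truth$otu$cag == "CAG1"]
  lin <- sim$taxonomy$lineage[match(cag1, sim$taxonomy$otu)]
  expect_true(all(grepl("Lactobacillus", lin)))
  expect_true(all(sim$taxonomy$confidence >= 0.8 &
                    sim$taxonomy$confidence <= 1))
})

test_that("truth records the rule onset day implied by each trajectory", {
  cfg <- small_sim_config()  # ramps start day 1/2, end day 8, |fc| 3
  sim <- simulate_study(cfg)
  tr <- sim$truth$cag
  # |traj| passes 1 strictly when frac > 1/3: CAG1 starts day 1 ->
  # frac(d) = (d-1)/7 > 1/3 at d = 4; CAG3 starts day 2 -> (d-2)/6 > 1/3 at d = 5
  expect_equal(tr$rule_onset_day[tr$cag == "CAG1"], 4L)
  expect_equal(tr$rule_onset_day[tr$cag == "CAG3"], 5L)
  expect_true(is.na(tr$rule_onset_day[tr$cag == "CAG2"]))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(days = 1:5), "day 0")
  expect_error(sim_config(groups = c("A", "A")), "distinct")
  expect_error(sim_config(n_otus = 10L), "exceeds n_otus")
  expect_error(sim_config(cag_log2fc = c(1, 2)), "match cag_sizes")
  expect_error(sim_config(extra_diff_log2fc = 1), "n_extra_differential")
  expect_error(sim_config(cag_ramp_start = rep(20L, 8)), "ramp starts")
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(n_subjects_per_group = 1L), ">= 2 subjects")
})

test_that("the default design matches its documented structure", {
  cfg <- default_paper_design(seed = 7)
  expect_equal(cfg$n_subjects_per_group, 10L)
  expect_equal(cfg$days, c(0:14, 28L, 84L))
  expect_equal(cfg$n_otus, 300L)
  expect_equal(cfg$cag_sizes, rep(8L, 8L))
  expect_equal(sum(cfg$cag_sizes[cfg$cag_log2fc != 0]) +
                 cfg$n_extra_differential, 50L)
  expect_true(all(abs(cfg$cag_log2fc[cfg$cag_log2fc != 0]) >= 2))
  expect_equal(cfg$seed, 7L)
})

test_that("write_simulation emits readable pipeline inputs", {
  sim <- simulate_study(small_sim_config())
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_identical(read_otu_table(file.path(dir, "otu_table.tsv")),
                   sim$counts)
  expect_equal(nrow(read_design(file.path(dir, "design.tsv"))),
               nrow(sim$design))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$otu, sim$taxonomy$otu)
})
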