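#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Inputs are either three
#' file paths (OTU table, design, taxonomy) or a [sim_config()] to generate
#' them; exactly one of the two must be given.
#'
#' @param otu_table,design,taxonomy Input file paths (taxonomy optional).
#' @param simulate A `sim_config` to generate inputs instead of reading
#'   them.
#' @param out_dir Output directory for the result bundle.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it (mandatory).
#' @param depth Rarefaction depth.
#' @param alpha_reps Rarefaction replicates averaged for alpha diversity.
#' @param n_permutations Permutations for the group PerMANOVA and each
#'   CAG-split test.
#' @param variance_fraction Cumulative PCoA variance the MANOVA axes must
#'   cover.
#' @param discrimination_window Inclusive day range whose samples train
#'   the random-forest group classifier. The default starts at day 10 so
#'   the forest sees the community after the treatment contrast has
#'   developed; widen it (e.g. `c(0, Inf)`) to train on the whole series.
#'   The leave-one-out error is evaluated on the last day in the window,
#'   using the selected key OTUs as features.
#' @param rf_trees,rf_repeats,mdia_threshold Random-forest settings.
#' @param run_rf If `FALSE`, skip the forest and use `key_otu_list`.
#' @param key_otu_list Optional explicit key-OTU vector overriding the
#'   forest selection as input to the co-abundance stage.
#' @param corr_group Group whose samples define the co-abundance window
#'   (the treated arm).
#' @param corr_window Inclusive day range of the co-abundance window.
#' @param cag_alpha,min_clade CAG tree-cut settings.
#' @param r_threshold Network edge threshold on |r|.
#' @param epsilon Pseudocount of the onset rule.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table = NULL, design = NULL, taxonomy = NULL,
                            simulate = NULL, out_dir, seed,
                            depth = 8000L, alpha_reps = 1000L,
                            n_permutations = 9999L,
                            variance_fraction = 0.8,
                            discrimination_window = c(10, Inf),
                            rf_trees = 1000L, rf_repeats = 10L,
                            mdia_threshold = 0.001,
                            run_rf = TRUE, key_otu_list = NULL,
                            corr_group = "CR", corr_window = c(0, 14),
                            cag_alpha = 0.001, min_clade = 3L,
                            r_threshold = 0.5, epsilon = 1e-6) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  if (is.null(simulate) && (is.null(otu_table) || is.null(design))) {
    stop("give either input paths (otu_table, design) or a sim_config")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    stop("'simulate' must be a sim_config")
  }
  if (!run_rf && is.null(key_otu_list)) {
    stop("run_rf = FALSE requires an explicit key_otu_list")
  }
  stopifnot(depth >= 1, alpha_reps >= 1, n_permutations >= 1,
            variance_fraction > 0, variance_fraction <= 1,
            mdia_threshold >= 0, cag_alpha > 0, cag_alpha < 1,
            min_clade >= 1, r_threshold >= 0, epsilon > 0,
            length(corr_window) == 2L, length(discrimination_window) == 2L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading (or simulation), rarefaction, alpha
#' diversity over repeated rarefactions, Bray-Curtis distances, PCoA,
#' group PerMANOVA, MANOVA on leading principal coordinates, per-day
#' Mann-Whitney tests along PC1, random-forest key-OTU selection with
#' leave-one-out error, within-subject correlation of the key OTUs,
#' CAG construction, network export, CAG dynamics with onset detection and
#' Kruskal-Wallis/Dunn baseline tests. Every artifact is written to
#' `config$out_dir` as UTF-8 TSV (plus GraphML and Newick), together with
#' `manifest.json` recording seeds, parameters and dropped samples.
#' Identical config and seed reproduce the bundle byte for byte.
#'
#' @param config `pipeline_config`.
#' @return Named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed,
                        c("rarefy", "alpha", "permanova", "rf", "cag"))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(cfg$out_dir, paste0(name, ".partial")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- inputs ---------------------------------------------------------
  stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_study(cfg$simulate)
      counts <- sim$counts
      design <- sim$design
      taxonomy <- sim$taxonomy
      write_tsv(sim$truth$otu, file.path(cfg$out_dir, "truth.tsv"))
      res$truth <- sim$truth
    } else {
      counts <- read_otu_table(cfg$otu_table)
      design <- read_design(cfg$design)
      taxonomy <- if (!is.null(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
    }
    covered <- rownames(counts) %in% design$sample
    if (!all(covered)) {
      stop("samples missing from the design: ",
           paste(rownames(counts)[!covered], collapse = ", "))
    }
    res$counts <- counts
    res$design <- validate_design(design)
    res$taxonomy <- taxonomy
  })

  ## -- rarefaction ----------------------------------------------------
  stage("rarefy", {
    rar <- rarefy(res$counts, cfg$depth, seed = seeds[["rarefy"]])
    dropped <- attr(rar, "dropped_samples")
    writeLines(dropped, file.path(cfg$out_dir, "dropped_samples.txt"))
    write_otu_table(rar, file.path(cfg$out_dir, "rarefied_otu_table.tsv"),
                    comment = paste0("rarefied:", cfg$depth, ":",
                                     seeds[["rarefy"]]))
    res$rarefied <- rar
    res$dropped <- dropped
    res$design <- res$design[res$design$sample %in% rownames(rar), ]
  })

  ## -- alpha diversity ------------------------------------------------
  stage("alpha", {
    alpha <- alpha_over_rarefactions(res$counts, depth = cfg$depth,
                                     n_reps = cfg$alpha_reps,
                                     seed = seeds[["alpha"]])
    write_tsv(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"))
    res$alpha <- alpha
  })

  ## -- beta diversity + ordination ------------------------------------
  stage("ordination", {
    ab <- relative_abundance(res$rarefied,
                             provenance = paste0("rarefied:", cfg$depth, ":",
                                                 seeds[["rarefy"]]))
    bc <- bray_curtis_matrix(ab)
    write_matrix_tsv(bc, file.path(cfg$out_dir, "bray_curtis.tsv"),
                     id_col = "sample")
    pc <- pcoa(bc)
    write_matrix_tsv(pc$coordinates,
                     file.path(cfg$out_dir, "pcoa_coordinates.tsv"),
                     id_col = "sample")
    write_tsv(data.frame(axis = paste0("PC", seq_along(pc$eigenvalues)),
                         eigenvalue = pc$eigenvalues,
                         proportion_explained = pc$proportion_explained),
              file.path(cfg$out_dir, "pcoa_eigenvalues.tsv"))
    res$abundance <- ab
    res$bray_curtis <- bc
    res$pcoa <- pc
  })

  ## -- group tests ----------------------------------------------------
  stage("group_tests", {
    labels <- res$design$group[match(rownames(res$bray_curtis),
                                     res$design$sample)]
    pm <- permanova(res$bray_curtis, labels,
                    n_permutations = cfg$n_permutations,
                    seed = seeds[["permanova"]])
    write_tsv(data.frame(pseudo_F = pm$pseudo_F, R2 = pm$R2,
                         p_value = pm$p_value,
                         n_permutations = pm$n_permutations,
                         seed = pm$seed),
              file.path(cfg$out_dir, "permanova.tsv"))
    mv <- manova_on_pcs(res$pcoa, labels,
                        variance_fraction = cfg$variance_fraction)
    write_tsv(data.frame(wilks_lambda = mv$statistic, approx_F = mv$approx_F,
                         p_value = mv$p_value, n_axes_used = mv$n_axes_used,
                         variance_covered = mv$variance_covered),
              file.path(cfg$out_dir, "manova.tsv"))
    axis1 <- axis_group_test(res$pcoa, axis = 1L, design = res$design)
    write_tsv(axis1, file.path(cfg$out_dir, "pc1_group_tests.tsv"))
    res$permanova <- pm
    res$manova <- mv
    res$pc1_tests <- axis1
  })

  ## -- random-forest discrimination ------------------------------------
  stage("discriminant", {
    if (cfg$run_rf) {
      win <- cfg$discrimination_window
      dd <- res$design[res$design$day >= win[[1L]] &
                         res$design$day <= win[[2L]], ]
      if (nrow(dd) < 3L) stop("discrimination window holds < 3 samples")
      sel <- select_key_otus(res$abundance[dd$sample, , drop = FALSE],
                             dd$group, n_trees = cfg$rf_trees,
                             threshold = cfg$mdia_threshold,
                             n_repeats = cfg$rf_repeats,
                             seed = seeds[["rf"]])
      keys <- key_otus(sel)
      if (length(keys) < 2L) {
        stop("fewer than 2 key OTUs selected by the forest")
      }
      eval_day <- max(dd$day)
      de <- dd[dd$day == eval_day, ]
      err <- loocv_error(
        res$abundance[de$sample, keys, drop = FALSE], de$group,
        n_trees = cfg$rf_trees, seed = seeds[["rf"]])
      write_tsv(sel$scores, file.path(cfg$out_dir, "rf_selection.tsv"))
      write_tsv(data.frame(window_start = win[[1L]], window_end = win[[2L]],
                           loocv_day = eval_day,
                           n_features = length(keys), loocv_error = err,
                           n_trees = cfg$rf_trees, seed = seeds[["rf"]]),
                file.path(cfg$out_dir, "rf_loocv.tsv"))
      res$rf <- sel
      res$loocv_error <- err
      res$key_otus <- key_otus(sel)
    }
    if (!is.null(cfg$key_otu_list)) res$key_otus <- cfg$key_otu_list
    if (length(res$key_otus) < 2L) {
      stop("fewer than 2 key OTUs; cannot build co-abundance groups")
    }
  })

  ## -- co-abundance groups --------------------------------------------
  stage("cag", {
    C <- repeated_corr(res$abundance, res$design, otus = res$key_otus,
                       group = cfg$corr_group, window_days = cfg$corr_window)
    write_matrix_tsv(unclass(C),
                     file.path(cfg$out_dir, "repeated_correlation.tsv"),
                     id_col = "otu")
    cags <- build_cags(C, alpha = cfg$cag_alpha,
                       n_permutations = cfg$n_permutations,
                       min_clade = cfg$min_clade, seed = seeds[["cag"]])
    write_tsv(data.frame(otu = names(cags$assignment),
                         cag = paste0("CAG", cags$assignment)),
              file.path(cfg$out_dir, "cag_assignment.tsv"))
    write_tsv(cags$splits, file.path(cfg$out_dir, "cag_splits.tsv"))
    writeLines(hclust_to_newick(cags$dendrogram),
               file.path(cfg$out_dir, "cag_dendrogram.nwk"))
    build_network(C, cags, res$taxonomy, r_threshold = cfg$r_threshold,
                  path = file.path(cfg$out_dir, "cag_network.graphml"))
    res$corr <- C
    res$cags <- cags
  })

  ## -- CAG dynamics ----------------------------------------------------
  stage("dynamics", {
    dyn <- cag_series(res$abundance, res$design, res$cags)
    write_tsv(dyn$per_sample, file.path(cfg$out_dir, "cag_per_sample.tsv"))
    write_tsv(dyn$by_day, file.path(cfg$out_dir, "cag_by_day.tsv"))
    cag_ids <- sort(unique(dyn$by_day$cag))
    onsets <- vapply(cag_ids, function(cid) {
      onset_day(dyn, cid, group = cfg$corr_group, epsilon = cfg$epsilon)
    }, integer(1L))
    write_tsv(data.frame(cag = cag_ids, onset_day = onsets),
              file.path(cfg$out_dir, "cag_onsets.tsv"))
    tests <- lapply(cag_ids, function(cid) {
      kd <- kw_dunn_vs_baseline(dyn, cid, group = cfg$corr_group)
      vb <- kd$vs_baseline
      if (is.null(vb)) return(NULL)
      data.frame(cag = cid, kruskal_p = kd$kruskal$p_value, vb,
                 stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, tests),
              file.path(cfg$out_dir, "cag_baseline_tests.tsv"))
    res$dynamics <- dyn
    res$onsets <- stats::setNames(onsets, cag_ids)
  })

  ## -- manifest --------------------------------------------------------
  stage("manifest", {
    manifest <- list(
      package = "cagdyn",
      version = as.character(utils::packageVersion("cagdyn")),
      master_seed = cfg$seed,
      stage_seeds = as.list(seeds),
      depth = cfg$depth,
      alpha_reps = cfg$alpha_reps,
      n_permutations = cfg$n_permutations,
      mdia_threshold = cfg$mdia_threshold,
      cag_alpha = cfg$cag_alpha,
      min_clade = cfg$min_clade,
      r_threshold = cfg$r_threshold,
      epsilon = cfg$epsilon,
      corr_group = cfg$corr_group,
      corr_window = cfg$corr_window,
      dropped_samples = res$dropped,
      n_samples_retained = nrow(res$rarefied),
      n_otus = ncol(res$rarefied),
      n_key_otus = length(res$key_otus),
      n_cags = length(unique(res$cags$assignment))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(res)
}

## named stage seeds derived deterministically from the master seed
derive_seeds <- function(master, names) {
  s <- withr::with_seed(as.integer(master),
                        sample.int(.Machine$integer.max, length(names)))
  stats::setNames(s, names)
}

## Newick serialization of an hclust tree, leaf names and branch heights
hclust_to_newick <- function(hc) {
  labels <- hc$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(hc$merge) + 1L))
  node_str <- function(node, parent_height) {
    if (node < 0L) {
      sprintf("%s:%s", labels[[-node]], format(parent_height, digits = 10))
    } else {
      h <- hc$height[[node]]
      kids <- hc$merge[node, ]
      sprintf("(%s,%s):%s",
              node_str(kids[[1L]], h), node_str(kids[[2L]], h),
              format(parent_height - h, digits = 10))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[[root]]
  kids <- hc$merge[root, ]
  sprintf("(%s,%s);", node_str(kids[[1L]], h), node_str(kids[[2L]], h))
}
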