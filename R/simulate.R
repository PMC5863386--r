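#' Simulation configuration for a longitudinal two-group microbiota study
#'
#' Bundles and validates every knob of the generative model used by
#' [simulate_study()]. See [default_paper_design()] for the standard
#' calorie-restriction-style design.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param days Integer study days (must include 0).
#' @param groups Two group labels; the second is the treated arm that
#'   receives the CAG trajectories.
#' @param n_otus Total OTUs.
#' @param cag_sizes Integer vector, one entry per planted CAG; the sum may
#'   not exceed `n_otus`. CAG members are the first `sum(cag_sizes)` OTUs.
#' @param cag_log2fc Per-CAG log2 fold change of the latent abundance at
#'   `ramp_end_day` in the treated group (0 = static CAG).
#' @param cag_ramp_start Per-CAG day the trajectory starts ramping.
#' @param n_extra_differential Standalone differential OTUs outside any
#'   CAG (they get individual trajectories but no shared factor).
#' @param extra_diff_log2fc,extra_diff_ramp_start Their trajectory
#'   parameters (lengths must equal `n_extra_differential`).
#' @param ramp_end_day Day every ramp reaches its endpoint (held constant
#'   afterwards).
#' @param dominant_base Latent log-abundance intercept of the first OTU of
#'   CAG 1, the planted dominant phylotype.
#' @param member_base_mean,member_base_sd Normal parameters of the latent
#'   intercepts of the remaining CAG-member OTUs.
#' @param background_base_mean,background_base_sd Same for non-CAG OTUs.
#' @param subject_sd SD of the per-subject, per-OTU random intercept
#'   (log scale).
#' @param cag_factor_sd SD of the shared per-(CAG, subject, day) latent
#'   factor that makes members of one CAG co-vary.
#' @param otu_noise_sd SD of the independent per-observation latent noise.
#' @param theta Dirichlet concentration of the count model; larger =
#'   less compositional overdispersion.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters.
#' @param seed Integer seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 10L,
                       days = c(0:14, 28L, 84L),
                       groups = c("NC", "CR"),
                       n_otus = 300L,
                       cag_sizes = rep(8L, 8L),
                       cag_log2fc = c(3, 2.5, 0, 0, -2.5, -3, -3, -3.5),
                       cag_ramp_start = c(1L, 0L, 0L, 0L, 2L, 4L, 1L, 3L),
                       n_extra_differential = 2L,
                       extra_diff_log2fc = c(3, -3),
                       extra_diff_ramp_start = c(2L, 3L),
                       ramp_end_day = 14L,
                       dominant_base = 3.2,
                       member_base_mean = 1.5,
                       member_base_sd = 0.6,
                       background_base_mean = 0,
                       background_base_sd = 1.5,
                       subject_sd = 0.5,
                       cag_factor_sd = 1.0,
                       otu_noise_sd = 0.4,
                       theta = 300,
                       depth_meanlog = log(15000),
                       depth_sdlog = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    days = sort(unique(as.integer(days))),
    groups = as.character(groups),
    n_otus = as.integer(n_otus),
    cag_sizes = as.integer(cag_sizes),
    cag_log2fc = as.numeric(cag_log2fc),
    cag_ramp_start = as.integer(cag_ramp_start),
    n_extra_differential = as.integer(n_extra_differential),
    extra_diff_log2fc = as.numeric(extra_diff_log2fc),
    extra_diff_ramp_start = as.integer(extra_diff_ramp_start),
    ramp_end_day = as.integer(ramp_end_day),
    dominant_base = dominant_base,
    member_base_mean = member_base_mean,
    member_base_sd = member_base_sd,
    background_base_mean = background_base_mean,
    background_base_sd = background_base_sd,
    subject_sd = subject_sd,
    cag_factor_sd = cag_factor_sd,
    otu_noise_sd = otu_noise_sd,
    theta = theta,
    depth_meanlog = depth_meanlog,
    depth_sdlog = depth_sdlog,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_subjects_per_group < 2L) stop("need >= 2 subjects per group")
    if (!0L %in% days) stop("days must include day 0 (baseline)")
    if (length(groups) != 2L || anyDuplicated(groups)) {
      stop("exactly 2 distinct group labels required")
    }
    if (sum(cag_sizes) + n_extra_differential > n_otus) {
      stop("sum(cag_sizes) + n_extra_differential exceeds n_otus")
    }
    if (any(cag_sizes < 1L)) stop("cag_sizes must be positive")
    if (length(cag_log2fc) != length(cag_sizes) ||
        length(cag_ramp_start) != length(cag_sizes)) {
      stop("cag_log2fc and cag_ramp_start must match cag_sizes in length")
    }
    if (length(extra_diff_log2fc) != n_extra_differential ||
        length(extra_diff_ramp_start) != n_extra_differential) {
      stop("extra_diff_log2fc and extra_diff_ramp_start must have length ",
           "n_extra_differential")
    }
    if (any(c(cag_ramp_start, extra_diff_ramp_start) < 0L |
            c(cag_ramp_start, extra_diff_ramp_start) >= ramp_end_day)) {
      stop("trajectory ramp starts must lie in [0, ramp_end_day)")
    }
    if (theta <= 0 || subject_sd < 0 || cag_factor_sd < 0 || otu_noise_sd < 0) {
      stop("variance and concentration parameters must be non-negative ",
           "(theta > 0)")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Standard study design mirrored by the simulator
#'
#' Two groups of 10 subjects; daily sampling days 0-14 plus sparse later
#' time points (28, 84); 300 OTUs of which 64 belong to 8 planted
#' co-abundance groups of 8 OTUs each. Six CAGs carry group-specific
#' piecewise-linear log2 trajectories (|log2 fold| >= 2 by day 14) and two
#' are static; the 48 dynamic-CAG members plus 2 standalone trajectory
#' OTUs give 50 differential OTUs. One dominant enriched OTU; read depths
#' roughly 8,000-30,000. CAG sizes of 8 keep every dendrogram split
#' statistically resolvable: a split into clades of sizes (a, b) has only
#' choose(a+b, a) distinct label assignments, so smaller planted CAGs
#' could never be separated at the 0.001 level.
#'
#' @param seed Integer seed stored in the config.
#' @return `sim_config`.
#' @export
default_paper_design <- function(seed = 1L) {
  sim_config(seed = seed)
}

## piecewise-linear log2 trajectory: 0 until ramp_start, linear to the
## endpoint at ramp_end_day, constant afterwards
cag_trajectory <- function(day, log2fc, ramp_start, ramp_end_day) {
  frac <- pmin(pmax((day - ramp_start) / (ramp_end_day - ramp_start), 0), 1)
  log2fc * frac
}

#' Simulate a longitudinal OTU count table with planted structure
#'
#' Generative model, per subject s, day d, OTU i:
#' latent log2-abundance lambda = base_i + u_is + traj_c(i)(d) * treated(s)
#' + f_{c(i),s,d} + e_isd, where u_is ~ N(0, subject_sd) is a per-subject
#' intercept, traj_c is the CAG's piecewise-linear trajectory (treated arm
#' only), f is a latent factor shared by all members of a CAG within one
#' (subject, day) so they co-vary, and e is independent noise. Expected
#' proportions are softmax(lambda * log 2); counts are
#' Dirichlet-multinomial: p ~ Dirichlet(theta * p_expected), reads ~
#' Multinomial(depth, p), depth ~ round(LogNormal).
#'
#' @param config `sim_config`.
#' @return List: `counts` (samples x OTUs integer matrix), `design`
#'   (data.frame sample/subject/group/day), `taxonomy` (otu/lineage/
#'   confidence), `truth` (list with per-OTU `otu` data.frame: `otu`,
#'   `cag`, `differential`, `log2fc`; per-CAG `cag` data.frame: `cag`,
#'   `size`, `log2fc`, `ramp_start`, `rule_onset_day` — the first
#'   simulated day with |trajectory| > 1; and `config`).
#' @export
simulate_study <- function(config = default_paper_design()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_cag <- length(cfg$cag_sizes)
  n_member <- sum(cfg$cag_sizes)
  n_extra <- cfg$n_extra_differential
  otu_ids <- sprintf("OTU%d", seq_len(cfg$n_otus))
  cag_of <- c(rep(seq_len(n_cag), cfg$cag_sizes),
              rep(NA_integer_, cfg$n_otus - n_member))
  extras <- if (n_extra > 0L) n_member + seq_len(n_extra) else integer()

  subjects <- paste0(rep(cfg$groups, each = cfg$n_subjects_per_group),
                     "_m", rep(seq_len(cfg$n_subjects_per_group), 2L))
  subj_group <- rep(cfg$groups, each = cfg$n_subjects_per_group)
  design <- expand.grid(subject = subjects, day = cfg$days,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$group <- subj_group[match(design$subject, subjects)]
  design$sample <- paste0(design$subject, "_d", design$day)
  design <- design[order(design$subject, design$day),
                   c("sample", "subject", "group", "day")]
  rownames(design) <- NULL

  withr::with_seed(cfg$seed, {
    base <- stats::rnorm(cfg$n_otus, cfg$background_base_mean,
                         cfg$background_base_sd)
    members <- which(!is.na(cag_of))
    base[c(members, extras)] <- stats::rnorm(n_member + n_extra,
                                             cfg$member_base_mean,
                                             cfg$member_base_sd)
    base[[1L]] <- cfg$dominant_base  # OTU1, first member of CAG1

    u <- matrix(stats::rnorm(length(subjects) * cfg$n_otus,
                             sd = cfg$subject_sd),
                nrow = length(subjects),
                dimnames = list(subjects, otu_ids))

    n_samples <- nrow(design)
    counts <- matrix(0L, nrow = n_samples, ncol = cfg$n_otus,
                     dimnames = list(design$sample, otu_ids))
    depths <- pmax(1L, as.integer(round(stats::rlnorm(
      n_samples, cfg$depth_meanlog, cfg$depth_sdlog))))

    treated <- cfg$groups[[2L]]
    for (si in seq_len(n_samples)) {
      subj <- design$subject[[si]]
      day <- design$day[[si]]
      lambda <- base + u[subj, ]
      if (design$group[[si]] == treated) {
        traj <- cag_trajectory(day, cfg$cag_log2fc, cfg$cag_ramp_start,
                               cfg$ramp_end_day)
        lambda[members] <- lambda[members] + traj[cag_of[members]]
        if (n_extra > 0L) {
          lambda[extras] <- lambda[extras] +
            cag_trajectory(day, cfg$extra_diff_log2fc,
                           cfg$extra_diff_ramp_start, cfg$ramp_end_day)
        }
      }
      f <- stats::rnorm(n_cag, sd = cfg$cag_factor_sd)
      lambda[members] <- lambda[members] + f[cag_of[members]]
      lambda <- lambda + stats::rnorm(cfg$n_otus, sd = cfg$otu_noise_sd)
      p_exp <- softmax(lambda * log(2))
      p <- rdirichlet1(cfg$theta * p_exp)
      counts[si, ] <- stats::rmultinom(1L, depths[[si]], p)[, 1L]
    }
    taxonomy <- synthetic_taxonomy(otu_ids, cag_of)
    list(counts = counts, taxonomy = taxonomy)
  }) -> drawn
  counts <- drawn$counts
  taxonomy <- drawn$taxonomy

  traj_days <- vapply(cfg$days, function(d) {
    cag_trajectory(d, cfg$cag_log2fc, cfg$cag_ramp_start, cfg$ramp_end_day)
  }, numeric(n_cag))
  if (n_cag == 1L) traj_days <- matrix(traj_days, nrow = 1L)
  rule_onset <- apply(traj_days, 1L, function(tr) {
    hit <- which(cfg$days > 0L & abs(tr) > 1)
    if (!length(hit)) NA_integer_ else cfg$days[hit[[1L]]]
  })

  otu_fc <- ifelse(is.na(cag_of), 0, cfg$cag_log2fc[cag_of])
  otu_fc[extras] <- cfg$extra_diff_log2fc
  truth <- list(
    otu = data.frame(
      otu = otu_ids,
      cag = ifelse(is.na(cag_of), NA_character_, paste0("CAG", cag_of)),
      differential = abs(otu_fc) >= 1e-9,
      log2fc = otu_fc,
      stringsAsFactors = FALSE
    ),
    cag = data.frame(
      cag = paste0("CAG", seq_len(n_cag)),
      size = cfg$cag_sizes,
      log2fc = cfg$cag_log2fc,
      ramp_start = cfg$cag_ramp_start,
      rule_onset_day = as.integer(rule_onset),
      stringsAsFactors = FALSE
    ),
    config = cfg
  )
  list(counts = counts, design = design, taxonomy = taxonomy, truth = truth)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## one Dirichlet draw via independent gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

## lineages drawn from a small pool typical of mouse gut communities;
## CAG1 is pinned to Lactobacillus so the dominant OTU carries the
## expected genus
synthetic_taxonomy <- function(otu_ids, cag_of) {
  pool <- c(
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Barnesiella",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Parabacteroides",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Roseburia",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Oscillibacter",
    "Bacteria;Firmicutes;Erysipelotrichia;Erysipelotrichales;Erysipelotrichaceae;Turicibacter",
    "Bacteria;Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Akkermansiaceae;Akkermansia",
    "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfovibrionales;Desulfovibrionaceae;Desulfovibrio",
    "Bacteria;Actinobacteria;Coriobacteriia;Coriobacteriales;Coriobacteriaceae;Enterorhabdus"
  )
  lineage <- sample(pool, length(otu_ids), replace = TRUE)
  lineage[which(cag_of == 1L)] <- pool[[1L]]
  data.frame(
    otu = otu_ids,
    lineage = lineage,
    confidence = round(stats::runif(length(otu_ids), 0.8, 1), 3),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `otu_table.tsv`, `design.tsv`,
#'   `taxonomy.tsv` and `truth.tsv` (per-OTU truth labels).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(sim$counts, file.path(dir, "otu_table.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(sim$truth$otu, file.path(dir, "truth.tsv"))
  invisible(dir)
}
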