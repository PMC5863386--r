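# Small programmatic fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(5L, 0L,
                0L, 5L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB")))
  m
}

# deterministic random count table
random_counts <- function(n_samples, n_otus, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_otus, lambda), nrow = n_samples,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                paste0("otu", seq_len(n_otus))))
    storage.mode(m) <- "integer"
    m
  })
}

toy_design <- function(subjects, days, group = "CR") {
  df <- expand.grid(subject = subjects, day = days,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$sample <- paste0(df$subject, "_d", df$day)
  df$group <- group
  df[, c("sample", "subject", "group", "day")]
}

# a small, fast simulation sharing the default design's structure
small_sim_config <- function(seed = 1) {
  sim_config(
    n_subjects_per_group = 5L,
    days = 0:10,
    n_otus = 60L,
    cag_sizes = c(8L, 8L, 8L),
    cag_log2fc = c(3, 0, -3),
    cag_ramp_start = c(1L, 0L, 2L),
    n_extra_differential = 0L,
    extra_diff_log2fc = numeric(),
    extra_diff_ramp_start = integer(),
    ramp_end_day = 8L,
    depth_meanlog = log(4000),
    depth_sdlog = 0.2,
    seed = seed
  )
}

# brute-force Bray-Curtis double loop (independent of vegan)
bc_brute <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  d
}

# brute-force within-subject correlation straight from the centered-sums
# formula, one pair at a time
repeated_corr_brute <- function(x, y, subject) {
  num <- 0; sx <- 0; sy <- 0
  for (s in unique(subject)) {
    idx <- subject == s
    dx <- x[idx] - mean(x[idx])
    dy <- y[idx] - mean(y[idx])
    num <- num + sum(dx * dy)
    sx <- sx + sum(dx^2)
    sy <- sy + sum(dy^2)
  }
  num / sqrt(sx * sy)
}
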