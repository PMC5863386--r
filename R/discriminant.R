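#' Random-forest key-OTU selection by mean decrease in accuracy
#'
#' Trains a random-forest classifier of group membership on OTU relative
#' abundances and scores every OTU by its unscaled permutation importance:
#' the mean decrease in out-of-bag accuracy (MDIA) when that OTU's values
#' are permuted. Because a single forest's importance estimates are noisy,
#' the forest is re-trained `n_repeats` times with distinct sub-seeds and
#' the per-OTU MDIA is averaged, with the standard error of the mean
#' reported. OTUs whose mean MDIA reaches `threshold` are flagged as
#' selected (key OTUs).
#'
#' Forest settings are the randomForest classification defaults, pinned
#' here for reproducibility: `ntree` trees, `mtry = floor(sqrt(p))`
#' candidate OTUs per split, trees grown to purity (nodesize 1), sampling
#' with replacement.
#'
#' @param ab Samples x OTUs abundance matrix.
#' @param labels Class label per sample (2+ classes, each with >= 2
#'   samples).
#' @param n_trees Trees per forest (default 1000).
#' @param threshold MDIA selection threshold on the raw accuracy scale
#'   (default 0.001).
#' @param n_repeats Forest re-trainings averaged (default 10).
#' @param seed Integer seed; the same seed reproduces the whole ensemble.
#' @return List of class `rf_selection`: `scores` (data.frame `otu`,
#'   `mdia`, `sem`, `rank`, `selected`, ranked by descending MDIA),
#'   `n_trees`, `threshold`, `n_repeats`, `seed`.
#' @export
select_key_otus <- function(ab, labels, n_trees = 1000L, threshold = 0.001,
                            n_repeats = 10L, seed = 1L) {
  labels <- check_rf_labels(labels, nrow(ab))
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_repeats))
  imp <- matrix(NA_real_, nrow = ncol(ab), ncol = n_repeats,
                dimnames = list(colnames(ab), NULL))
  for (r in seq_len(n_repeats)) {
    fit <- withr::with_seed(sub_seeds[[r]], {
      randomForest::randomForest(x = ab, y = labels, ntree = n_trees,
                                 importance = TRUE)
    })
    imp[, r] <- randomForest::importance(fit, type = 1L,
                                         scale = FALSE)[, 1L]
  }
  mdia <- rowMeans(imp)
  sem <- apply(imp, 1L, stats::sd) / sqrt(n_repeats)
  ord <- order(mdia, decreasing = TRUE)
  scores <- data.frame(
    otu = colnames(ab)[ord],
    mdia = mdia[ord],
    sem = sem[ord],
    rank = seq_len(ncol(ab)),
    selected = mdia[ord] >= threshold,
    stringsAsFactors = FALSE
  )
  rownames(scores) <- NULL
  structure(list(scores = scores, n_trees = as.integer(n_trees),
                 threshold = threshold, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat(sprintf("Random-forest key-OTU selection: %d/%d OTUs with MDIA >= %g\n",
              sum(x$scores$selected), nrow(x$scores), x$threshold))
  print(utils::head(x$scores, 10L))
  invisible(x)
}

#' Key OTUs of a selection
#' @param x `rf_selection`.
#' @return Character vector of selected OTU IDs, in rank order.
#' @export
key_otus <- function(x) {
  stopifnot(inherits(x, "rf_selection"))
  x$scores$otu[x$scores$selected]
}

#' Leave-one-out cross-validated classification error
#'
#' Holds out each sample in turn, retrains the forest on the rest, and
#' reports the fraction of held-out samples misclassified.
#'
#' @inheritParams select_key_otus
#' @return Error fraction in \[0, 1\].
#' @export
loocv_error <- function(ab, labels, n_trees = 1000L, seed = 1L) {
  labels <- check_rf_labels(labels, nrow(ab), min_per_class = 1L)
  n <- nrow(ab)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  fold_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  wrong <- 0L
  for (i in seq_len(n)) {
    train_y <- droplevels(labels[-i])
    if (nlevels(train_y) < 2L) { # held-out sample was a singleton class
      wrong <- wrong + 1L
      next
    }
    pred <- withr::with_seed(fold_seeds[[i]], {
      fit <- randomForest::randomForest(x = ab[-i, , drop = FALSE],
                                        y = train_y, ntree = n_trees)
      stats::predict(fit, ab[i, , drop = FALSE])
    })
    wrong <- wrong + as.integer(as.character(pred) != as.character(labels[[i]]))
  }
  wrong / n
}

check_rf_labels <- function(labels, n, min_per_class = 2L) {
  labels <- factor(labels)
  if (length(labels) != n) stop("labels must match the number of samples")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < min_per_class)) {
    stop("every class needs >= ", min_per_class, " samples")
  }
  labels
}
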