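#' Within-subject (repeated-observations) correlation between OTUs
#'
#' In a longitudinal design the naive correlation across all samples mixes
#' between-subject differences with within-subject co-variation. Following
#' the repeated-observations approach of Bland and Altman, each subject's
#' mean is removed from each OTU's series and the correlation is computed
#' on the pooled residuals:
#' r = sum_s sum_t (x_st - xbar_s)(y_st - ybar_s) /
#'     sqrt( sum(x - xbar_s)^2 * sum(y - ybar_s)^2 ).
#' Subject-specific offsets therefore cancel and only within-subject
#' temporal co-variation remains.
#'
#' By default the correlation window is restricted to one group and a day
#' range, matching the practice of estimating co-abundance on the treated
#' arm during the dynamic phase of an intervention.
#'
#' @param ab Samples x OTUs abundance matrix.
#' @param design Study design covering the samples of `ab`.
#' @param otus OTU IDs to correlate (default: all columns).
#' @param group Group to restrict to (`NULL` = all groups).
#' @param window_days Length-2 inclusive day range (default `c(0, 14)`).
#' @return Symmetric correlation matrix with unit diagonal and class
#'   `repeated_corr`; attributes `n_subjects`, `n_observations`, and
#'   `undefined_otus` (OTUs with zero within-subject variance, whose rows
#'   and columns are `NA` off the diagonal).
#' @export
repeated_corr <- function(ab, design, otus = colnames(ab), group = NULL,
                          window_days = c(0, 14)) {
  design <- validate_design(design)
  otus <- as.character(otus)
  missing_otus <- setdiff(otus, colnames(ab))
  if (length(missing_otus)) {
    stop("OTUs absent from the abundance table: ",
         paste(missing_otus, collapse = ", "))
  }
  keep <- design$sample %in% rownames(ab) &
    design$day >= window_days[[1L]] & design$day <= window_days[[2L]]
  if (!is.null(group)) keep <- keep & design$group == group
  design <- design[keep, , drop = FALSE]
  obs_per_subject <- table(design$subject)
  design <- design[design$subject %in%
                     names(obs_per_subject)[obs_per_subject >= 2L], ,
                   drop = FALSE]
  if (nrow(design) < 4L) {
    stop("need >= 2 subjects with >= 2 observations inside the window")
  }
  X <- ab[design$sample, otus, drop = FALSE]
  subj <- factor(design$subject)
  centered <- X - rowsum(X, subj)[subj, , drop = FALSE] /
    as.vector(table(subj))[subj]
  cp <- crossprod(centered)
  ss <- diag(cp)
  undefined <- otus[ss <= .Machine$double.eps * nrow(centered)]
  ss[ss == 0] <- NA_real_
  # normalize by sqrt(ss_i * ss_j) (not sqrt(ss_i) * sqrt(ss_j)): for a
  # perfectly co-varying pair the numerator equals ss, and sqrt of the
  # rounded square returns it exactly, so r is exactly 1
  r <- cp / sqrt(outer(ss, ss))
  diag(r) <- 1
  dimnames(r) <- list(otus, otus)
  structure(r, class = c("repeated_corr", class(r)),
            n_subjects = nlevels(subj),
            n_observations = nrow(design),
            undefined_otus = undefined)
}
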