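#' Read a classic tab-delimited OTU table
#'
#' Reads the QIIME-classic dialect: an optional leading line starting with
#' `#` (e.g. `# Constructed from biom file`), then a header row whose first
#' field names the OTU-ID column and whose remaining fields are sample IDs,
#' then one row per OTU of integer counts. The returned matrix is oriented
#' samples x OTUs, the layout every downstream function consumes.
#'
#' @param path Path to a tab-delimited OTU table.
#' @return Integer matrix, samples as rows and OTUs as columns, with
#'   sample IDs as rownames and OTU IDs as colnames.
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("OTU table at '", path, "' has no data rows")
  ## tolerate one leading comment line before the header
  if (startsWith(lines[[1L]], "#") && length(lines) >= 2L &&
      length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]) <
      length(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]])) {
    lines <- lines[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- fields[-1L]
  otu_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU IDs: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  n_s <- length(sample_ids)
  counts <- matrix(0L, nrow = n_s, ncol = length(otu_ids),
                   dimnames = list(sample_ids, otu_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_s + 1L) {
      stop("row for OTU '", otu_ids[[i]], "' has ", length(row) - 1L,
           " fields, expected ", n_s)
    }
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(vals) | vals != round(vals) | vals < 0)
    if (length(bad)) {
      stop("non-integer count '", row[-1L][bad[[1L]]], "' at OTU '",
           otu_ids[[i]], "', sample '", sample_ids[bad[[1L]]], "'")
    }
    counts[, i] <- as.integer(vals)
  }
  validate_otu_table(counts)
  counts
}

#' Write an OTU table in the classic tab-delimited layout
#'
#' @param counts Samples x OTUs integer matrix.
#' @param path Output path.
#' @param comment Optional leading comment line (written with a `#` prefix).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path, comment = NULL) {
  validate_otu_table(counts)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con, sep = "\n", useBytes = TRUE)
  }
  header <- paste(c("#OTU ID", rownames(counts)), collapse = "\t")
  rows <- vapply(seq_len(ncol(counts)), function(j) {
    paste(c(colnames(counts)[j], format(counts[, j], scientific = FALSE,
                                        trim = TRUE)), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Validate a samples x OTUs count matrix
#'
#' @param counts Matrix to check.
#' @return `TRUE`, invisibly; errors describe the first violated invariant.
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts)) stop("OTU table must be a matrix (samples x OTUs)")
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("OTU table needs at least one sample and one OTU")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("OTU table must carry sample IDs (rownames) and OTU IDs (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU IDs")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("OTU table must contain non-negative integer counts")
  }
  invisible(TRUE)
}

#' Read a sample metadata (study design) table
#'
#' Expects a tab-delimited file with header columns `sample`, `subject`,
#' `group` and `day`. Each row maps one sequenced sample to the subject it
#' came from, the subject's treatment group, and the study day.
#'
#' @param path Path to the design TSV.
#' @return A data.frame with columns `sample`, `subject`, `group` (factor)
#'   and `day` (integer).
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(df)
}

#' Validate a study design data.frame
#'
#' @param df data.frame with `sample`, `subject`, `group`, `day` columns.
#' @return The validated design (day coerced to integer, group to factor).
#' @export
validate_design <- function(df) {
  needed <- c("sample", "subject", "group", "day")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  df$sample <- as.character(df$sample)
  df$subject <- as.character(df$subject)
  df$day <- as.integer(df$day)
  if (anyNA(df$day) || any(df$day < 0)) stop("day must be a non-negative integer")
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in design")
  key <- paste(df$subject, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("duplicate (subject, day) pairs in design: ",
         paste(paste0(dup$subject, "/day", dup$day), collapse = ", "))
  }
  df$group <- factor(df$group)
  df
}

#' Write a study design table
#' @param design Design data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write_tsv(validate_design(design), path)
}

#' Read an OTU taxonomy table
#'
#' Tab-delimited with header columns `otu`, `lineage`, `confidence`; the
#' lineage is a semicolon-separated ranked string
#' (kingdom;phylum;class;order;family;genus), with missing ranks left as
#' empty fields rather than dropped.
#'
#' @param path Path to the taxonomy TSV.
#' @return data.frame with columns `otu`, `lineage`, `confidence`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("otu", "lineage", "confidence")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  df$otu <- as.character(df$otu)
  if (anyDuplicated(df$otu)) stop("duplicate OTU IDs in taxonomy")
  df$confidence <- as.numeric(df$confidence)
  if (anyNA(df$confidence) || any(df$confidence < 0 | df$confidence > 1)) {
    stop("taxonomy confidence must lie in [0, 1]")
  }
  df
}

#' Extract one rank from semicolon-separated lineages
#'
#' @param lineage Character vector of `k__;p__;...`-style or plain
#'   semicolon-separated lineages.
#' @param rank 1-based rank index (1 = kingdom, 2 = phylum, ...).
#' @return Character vector; `"unassigned"` where the rank is absent/empty.
#' @export
lineage_rank <- function(lineage, rank = 2L) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) < rank) return("unassigned")
    v <- trimws(p[[rank]])
    v <- sub("^[a-z]__", "", v)
    if (!nzchar(v)) "unassigned" else v
  }, character(1L))
  out
}

## shared TSV writer: UTF-8, tab-separated, newline-terminated, no quoting
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "", eol = "\n")
  invisible(path)
}

## labeled square matrix writer (distance/correlation matrices)
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}
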