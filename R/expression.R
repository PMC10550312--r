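DEFAULT_TISSUES <- c("leaf_tip", "leaf_middle", "leaf_base", "root", "shoot",
                     "ear", "anther", "tassel", "endosperm", "embryo")

#' Convert read counts to transcripts per million
#'
#' Standard TPM normalization: per-gene read counts are divided by effective
#' gene length, and each column (tissue/sample) is scaled so the rates sum
#' to one million. When several columns belong to the same tissue (sequencing
#' replicates) pass `tissue_of` to sum their counts before normalization,
#' which approximates merging replicate reads prior to counting.
#'
#' @param counts Numeric matrix, genes x tissues, with rownames.
#' @param lengths Effective gene lengths in bp, one per row (named or in
#'   row order); must be positive.
#' @param tissue_of Optional character vector, one tissue name per column of
#'   `counts`; columns sharing a name are summed.
#' @return Matrix of TPM values with the same rownames; each column sums to
#'   1e6.
#' @export
counts_to_tpm <- function(counts, lengths, tissue_of = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("gene lengths must be positive")
  if (!is.null(tissue_of)) {
    stopifnot(length(tissue_of) == ncol(counts))
    counts <- vapply(unique(tissue_of), function(t) {
      rowSums(counts[, tissue_of == t, drop = FALSE])
    }, numeric(nrow(counts)))
  }
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero total counts in column(s): ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  tpm
}

#' Assign expression categories from tissue TPM profiles
#'
#' A gene is `constitutive` when TPM >= `threshold` in every tissue,
#' `silent` when TPM < `threshold` in every tissue, and `tissue_specific`
#' otherwise (expressed in at least one tissue and not expressed in at
#' least one other). Genes with missing values are `undefined`.
#'
#' @param tpm Matrix genes x tissues (rownames = gene IDs).
#' @param threshold Expressed/not-expressed TPM cutoff (default 1).
#' @return data.table `gene_id`, `category` (factor: tissue_specific,
#'   constitutive, silent, undefined).
#' @export
categorize_expression <- function(tpm, threshold = 1) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) == 0L || nrow(tpm) == 0L) stop("empty TPM matrix")
  expressed <- tpm >= threshold
  n_on <- rowSums(expressed)
  n_def <- rowSums(!is.na(expressed))
  cat <- rep("undefined", nrow(tpm))
  ok <- n_def == ncol(tpm)
  cat[ok & n_on == ncol(tpm)] <- "constitutive"
  cat[ok & n_on == 0] <- "silent"
  cat[ok & n_on > 0 & n_on < ncol(tpm)] <- "tissue_specific"
  data.table(gene_id = rownames(tpm),
             category = factor(cat, levels = c("tissue_specific",
                                               "constitutive", "silent",
                                               "undefined")))
}

#' Log-transform TPM values for display
#'
#' `log10(tpm + pseudocount)`; the pseudocount (default 1) avoids problems
#' with zero values, so 0 maps to 0.
#'
#' @param tpm Numeric vector or matrix of non-negative TPM values.
#' @param pseudocount Added before taking log10 (default 1).
#' @return Transformed values, same shape as the input.
#' @export
log_tpm <- function(tpm, pseudocount = 1) {
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM values")
  log10(tpm + pseudocount)
}

#' Read a delimited gene x tissue expression matrix
#'
#' First column = gene IDs, remaining columns = tissues; "NA" tolerated.
#'
#' @param path Delimited text file (tab or comma separated, with header).
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, header = TRUE, na.strings = c("NA", ""))
  m <- as.matrix(dt[, -1L, with = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Write a gene x tissue expression matrix as tab-delimited text
#'
#' @param m Matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  dt <- data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
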