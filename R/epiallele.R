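EPIALLELE_LABELS <- c("UM", "gbM", "teM", "undetermined", "low_coverage")
DEFINED_EPIALLELES <- c("UM", "gbM", "teM")

#' Epiallele-calling thresholds
#'
#' Coverage and methylation-level thresholds used to assign each gene one
#' epiallele label from its CDS methylation summary. A gene needs at least
#' `min_sites_CG` covered CG cytosines and `min_sites_CHG` covered CHG
#' cytosines; otherwise it is `low_coverage`. Among covered genes:
#' UM requires both mCG and mCHG at or below `um_max`; gbM requires mCG at
#' or above `gbm_min_mCG` with mCHG at or below `um_max`; teM requires both
#' mCG and mCHG at or above `tem_min`. Genes with intermediate values are
#' `undetermined`. With `boundary_inclusive = FALSE` the comparisons become
#' strict (`<` / `>`), a published alternative reading of the rule; the
#' difference only affects genes sitting exactly on a threshold.
#'
#' @param min_sites_CG,min_sites_CHG Minimum covered cytosines per context
#'   (default 40 each).
#' @param um_max UM/gbM ceiling on mCHG and UM ceiling on mCG (default 0.05).
#' @param gbm_min_mCG gbM floor on mCG (default 0.2).
#' @param tem_min teM floor on both mCG and mCHG (default 0.4).
#' @param boundary_inclusive Use inclusive comparisons (default TRUE).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(min_sites_CG = 40L, min_sites_CHG = 40L,
                             um_max = 0.05, gbm_min_mCG = 0.2,
                             tem_min = 0.4, boundary_inclusive = TRUE) {
  stopifnot(um_max >= 0, um_max < gbm_min_mCG, gbm_min_mCG < tem_min,
            tem_min <= 1)
  structure(list(min_sites_CG = as.integer(min_sites_CG),
                 min_sites_CHG = as.integer(min_sites_CHG),
                 um_max = um_max, gbm_min_mCG = gbm_min_mCG,
                 tem_min = tem_min,
                 boundary_inclusive = isTRUE(boundary_inclusive)),
            class = "threshold_config")
}

#' Assign epiallele labels from CDS methylation summaries
#'
#' @param gm data.frame with columns `gene_id`, `mCG`, `mCHG`,
#'   `n_sites_CG`, `n_sites_CHG` (as produced by [genome_methylation()];
#'   extra columns such as `mCHH` are carried through). Undefined levels
#'   (NA, zero covered sites) yield `low_coverage`.
#' @param cfg A [threshold_config()].
#' @return data.table `gene_id`, `mCG`, `mCHG`, `n_sites_CG`, `n_sites_CHG`,
#'   `label` (factor with levels UM, gbM, teM, undetermined, low_coverage).
#' @export
call_epiallele <- function(gm, cfg = threshold_config()) {
  gm <- as.data.table(gm)
  need <- c("gene_id", "mCG", "mCHG", "n_sites_CG", "n_sites_CHG")
  stopifnot(all(need %in% names(gm)))
  le <- if (cfg$boundary_inclusive) `<=` else `<`
  ge <- if (cfg$boundary_inclusive) `>=` else `>`
  lowcov <- gm$n_sites_CG < cfg$min_sites_CG |
    gm$n_sites_CHG < cfg$min_sites_CHG |
    is.na(gm$mCG) | is.na(gm$mCHG)
  mcg <- gm$mCG
  mchg <- gm$mCHG
  label <- rep("undetermined", nrow(gm))
  label[le(mcg, cfg$um_max) & le(mchg, cfg$um_max)] <- "UM"
  label[ge(mcg, cfg$gbm_min_mCG) & le(mchg, cfg$um_max)] <- "gbM"
  label[ge(mcg, cfg$tem_min) & ge(mchg, cfg$tem_min)] <- "teM"
  label[lowcov] <- "low_coverage"
  out <- copy(gm)[, label := factor(label, levels = EPIALLELE_LABELS)]
  out[]
}

#' Call epialleles for a genome and summarize label counts
#'
#' @param gm Per-gene methylation table (see [call_epiallele()]); duplicate
#'   gene IDs are an error.
#' @param cfg A [threshold_config()].
#' @return List with `calls` (per-gene table) and `summary` (per-label
#'   `n` plus `fraction` of genes among those passing the coverage rule;
#'   fractions are NA when every gene is low_coverage).
#' @export
call_genome <- function(gm, cfg = threshold_config()) {
  gm <- as.data.table(gm)
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene_id in methylation table")
  calls <- call_epiallele(gm, cfg)
  n <- as.vector(table(calls$label))
  summary <- data.table(label = factor(EPIALLELE_LABELS, levels = EPIALLELE_LABELS),
                        n = n)
  covered <- sum(summary$n[summary$label != "low_coverage"])
  summary[, fraction := fifelse(label == "low_coverage", NA_real_,
                                if (covered > 0) n / covered else NA_real_)]
  list(calls = calls, summary = summary[])
}

#' Export teM genes as a BED track
#'
#' Writes a 6-column BED file (0-based half-open) of genes labelled teM,
#' suitable for display as a genome-browser flagging track.
#'
#' @param calls Per-gene call table from [call_epiallele()].
#' @param models The matching [gene_models()] object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_tem_bed <- function(calls, models, path) {
  calls <- as.data.table(calls)
  tem <- calls[label == "teM", gene_id]
  g <- models$genes[gene_id %in% tem]
  bed <- g[, .(chrom, start, end, name = gene_id, score = 0L, strand)]
  setorder(bed, chrom, start)
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
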