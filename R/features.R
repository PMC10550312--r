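#' Merged intersection of two interval sets
#'
#' Computes the overlap between two interval lists, merging the overlap
#' segments before summing so that overlapping annotations (e.g. nested TE
#' records) are counted once.
#'
#' @param a,b data.frames of intervals (`start`, `end`, 0-based half-open;
#'   optional `chrom` column restricts overlap to matching chromosomes).
#' @return List with `length` (total merged overlap in bp) and `segments`
#'   (data.table of merged overlap intervals).
#' @export
intersect_and_merge <- function(a, b) {
  a <- as.data.table(a)
  b <- as.data.table(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(length = 0L,
                segments = data.table(start = integer(), end = integer())))
  }
  if (!"chrom" %in% names(a)) a <- copy(a)[, chrom := "."]
  if (!"chrom" %in% names(b)) b <- copy(b)[, chrom := "."]
  ra <- merge_intervals(a[, .(chrom, start, end)])
  rb <- merge_intervals(b[, .(chrom, start, end)])
  x <- ra[, .(chrom, s = start, e = end)]
  y <- rb[, .(chrom, s = start, e = end)]
  setkey(y, chrom, s, e)
  ov <- foverlaps(x, y, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) {
    return(list(length = 0L,
                segments = data.table(start = integer(), end = integer())))
  }
  seg <- ov[, .(chrom, start = pmax(s, i.s), end = pmin(e, i.e))]
  seg <- seg[end > start]
  seg <- merge_intervals(seg)
  list(length = sum(seg$end - seg$start), segments = seg[])
}

#' Per-gene structural feature table
#'
#' Computes cumulative UTR/CDS/exon/intron lengths, exon counts, TE-overlap
#' quantities and a syntenic-homolog flag for every gene in a collection.
#' Lengths are cumulative: the individual elements of a gene are summed to
#' yield a single value per gene.
#'
#' @param models A [gene_models()] object.
#' @param te Optional TE/repeat annotation: data.frame with `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `superfamily`.
#'   Records without a superfamily label contribute to overlap lengths but
#'   are excluded from the superfamily sets (with a warning).
#' @param synteny Optional data.frame `gene_id`, `synteny` (logical) marking
#'   genes with a syntenic homolog in an outgroup genome (e.g. sorghum).
#'   Genes absent from the table get NA.
#' @param cds_te_min_bp Threshold for the CDS-TE overlap flag (default 100).
#' @param cds_te_strict If TRUE (default) the flag requires overlap strictly
#'   greater than `cds_te_min_bp`; if FALSE, at least `cds_te_min_bp`.
#' @return data.table with one row per gene: `gene_id`, `utr_len_total`,
#'   `cds_len`, `exon_len_total`, `intron_len_total`, `exon_count`,
#'   `intron_te_len_total`, `cds_te_overlap_len`, `has_utr`,
#'   `has_cds_te_ge100`, `te_superfamilies_in_introns` (list column of
#'   character vectors), `synteny_sorghum`.
#' @export
feature_table <- function(models, te = NULL, synteny = NULL,
                          cds_te_min_bp = 100L, cds_te_strict = TRUE) {
  g <- models$genes
  len_by_gene <- function(tab) {
    if (nrow(tab) == 0L) return(data.table(gene_id = character(), len = integer()))
    tab[, .(len = sum(end - start)), by = gene_id]
  }
  out <- data.table(gene_id = g$gene_id)
  add_len <- function(out, tab, col) {
    l <- len_by_gene(tab)
    v <- l$len[match(out$gene_id, l$gene_id)]
    data.table::set(out, j = col, value = fifelse(is.na(v), 0L, as.integer(v)))
    out
  }
  out <- add_len(out, rbind(models$utr5, models$utr3), "utr_len_total")
  out <- add_len(out, models$cds, "cds_len")
  out <- add_len(out, models$exons, "exon_len_total")
  ec <- models$exons[, .N, by = gene_id]
  out[, exon_count := {
    v <- ec$N[match(gene_id, ec$gene_id)]
    fifelse(is.na(v), 0L, v)
  }]
  introns <- models$exons[, derive_introns(.SD), by = gene_id,
                          .SDcols = c("start", "end")]
  chrom_of <- setNames(g$chrom, g$gene_id)
  if (nrow(introns)) introns[, chrom := chrom_of[gene_id]]
  out <- add_len(out, introns, "intron_len_total")
  nutr <- rbind(models$utr5, models$utr3)[, .N, by = gene_id]
  out[, has_utr := gene_id %in% nutr$gene_id]

  out[, intron_te_len_total := 0L]
  out[, cds_te_overlap_len := 0L]
  data.table::set(out, j = "te_superfamilies_in_introns",
                  value = list(rep(list(character()), nrow(out))))
  if (!is.null(te) && nrow(as.data.table(te))) {
    te <- as.data.table(te)
    if (!"superfamily" %in% names(te)) te[, superfamily := NA_character_]
    if (anyNA(te$superfamily)) {
      warning(sum(is.na(te$superfamily)),
              " TE record(s) without superfamily label; excluded from",
              " superfamily sets")
    }
    te_len <- function(iv) {
      # merged TE overlap per gene, vectorized across all genes
      if (nrow(iv) == 0L) return(data.table(gene_id = character(), len = integer()))
      x <- iv[, .(gene_id, chrom, s = start, e = end)]
      y <- merge_intervals(te[, .(chrom, start, end)])
      y <- y[, .(chrom, s = start, e = end)]
      setkey(y, chrom, s, e)
      ov <- foverlaps(x, y, type = "any", nomatch = NULL)
      ov <- ov[, .(gene_id, start = pmax(s, i.s), end = pmin(e, i.e))]
      ov <- ov[end > start]
      if (nrow(ov) == 0L) return(data.table(gene_id = character(), len = integer()))
      ir <- S4Vectors::split(IRanges::IRanges(ov$start + 1L, ov$end), ov$gene_id)
      lens <- sum(IRanges::width(IRanges::reduce(ir)))
      data.table(gene_id = names(lens), len = as.integer(lens))
    }
    it <- te_len(introns)
    v <- it$len[match(out$gene_id, it$gene_id)]
    out[, intron_te_len_total := fifelse(is.na(v), 0L, as.integer(v))]
    ct <- te_len(models$cds)
    v <- ct$len[match(out$gene_id, ct$gene_id)]
    out[, cds_te_overlap_len := fifelse(is.na(v), 0L, as.integer(v))]

    # superfamily presence in introns: each superfamily once per gene
    if (nrow(introns)) {
      x <- introns[, .(gene_id, chrom, s = start, e = end)]
      y <- te[!is.na(superfamily), .(chrom, s = start, e = end, superfamily)]
      if (nrow(y)) {
        setkey(y, chrom, s, e)
        ovsf <- foverlaps(x, y, type = "any", nomatch = NULL)
        ovsf <- ovsf[pmin(e, i.e) > pmax(s, i.s)]
        sf <- unique(ovsf[, .(gene_id, superfamily)])
        sets <- sf[, .(set = list(sort(superfamily))), by = gene_id]
        idx <- match(out$gene_id, sets$gene_id)
        out[, te_superfamilies_in_introns :=
              ifelse(is.na(idx), list(character()), sets$set[idx])]
      }
    }
  }
  cmp <- if (cds_te_strict) `>` else `>=`
  out[, has_cds_te_ge100 := cmp(cds_te_overlap_len, cds_te_min_bp)]
  out[, synteny_sorghum := NA]
  if (!is.null(synteny)) {
    syn <- as.data.table(synteny)
    stopifnot(all(c("gene_id", "synteny") %in% names(syn)))
    out[, synteny_sorghum := syn$synteny[match(gene_id, syn$gene_id)]]
  }
  out[]
}

#' Summaries of feature distributions by epiallele label
#'
#' @param features Table from [feature_table()].
#' @param calls Per-gene epiallele calls ([call_epiallele()]).
#' @return data.table of per-label medians and proportions for the main
#'   structural quantities.
#' @export
feature_summary_by_epiallele <- function(features, calls) {
  dt <- merge(as.data.table(features),
              as.data.table(calls)[, .(gene_id, label)], by = "gene_id")
  dt[, .(
    n = .N,
    median_utr_len = as.numeric(median(utr_len_total)),
    median_cds_len = as.numeric(median(cds_len)),
    median_exon_len = as.numeric(median(exon_len_total)),
    median_intron_len = as.numeric(median(intron_len_total)),
    median_intron_te_len = as.numeric(median(intron_te_len_total)),
    mean_exon_count = mean(exon_count),
    prop_no_utr = mean(!has_utr),
    prop_cds_te = mean(has_cds_te_ge100),
    prop_synteny = mean(synteny_sorghum, na.rm = TRUE)
  ), by = label][order(label)]
}

#' Read TE/repeat annotations from BED text
#'
#' Expects at least 3 columns (chrom, start, end; 0-based half-open); a
#' 4th column, when present, is taken as the superfamily label.
#'
#' @param path BED file path.
#' @return data.table `chrom`, `start`, `end`, `superfamily`.
#' @export
read_te_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", na.strings = c("NA", "."))
  setnames(dt, seq_len(min(4L, ncol(dt))),
           c("chrom", "start", "end", "superfamily")[seq_len(min(4L, ncol(dt)))])
  if (!"superfamily" %in% names(dt)) dt[, superfamily := NA_character_]
  dt[, .(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), superfamily = as.character(superfamily))]
}
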