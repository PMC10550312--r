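#' Weighted methylation level of a region set
#'
#' Computes per-context methylation of a gene from its CDS intervals. The
#' default is the read-weighted level: sum of methylated reads divided by
#' sum of total reads over all covered cytosines of that context inside the
#' regions. A cytosine counts as covered when its total read count is at
#' least 1. The alternative `method = "site_mean"` averages per-site levels
#' (each covered site weighted equally) and is provided for sensitivity
#' checks.
#'
#' Overlapping regions are merged before accumulation so no site is counted
#' twice.
#'
#' @param sites Site table ([read_cgmap()] columns).
#' @param regions data.frame of intervals (`chrom`, `start`, `end`; 0-based
#'   half-open), typically the gene's CDS.
#' @param gene_id Optional gene identifier carried into the result.
#' @param method `"weighted"` (default) or `"site_mean"`.
#' @return One-row data.table: `gene_id`, `mCG`, `mCHG`, `mCHH` (NA when a
#'   context has zero covered sites), `n_sites_CG`, `n_sites_CHG`,
#'   `n_sites_CHH`.
#' @export
region_methylation <- function(sites, regions, gene_id = NA_character_,
                               method = c("weighted", "site_mean")) {
  method <- match.arg(method)
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L) stop("empty region set")
  regions <- merge_intervals(regions)
  sel <- filter_sites(as.data.table(sites), regions)
  sel <- sel[n_total >= 1L]
  out <- data.table(gene_id = gene_id, mCG = NA_real_, mCHG = NA_real_,
                    mCHH = NA_real_, n_sites_CG = 0L, n_sites_CHG = 0L,
                    n_sites_CHH = 0L)
  for (ctx in VALID_CONTEXTS) {
    s <- sel[context == ctx]
    lev_col <- paste0("m", ctx)
    n_col <- paste0("n_sites_", ctx)
    out[[n_col]] <- nrow(s)
    if (nrow(s)) {
      out[[lev_col]] <- if (method == "weighted") {
        sum(s$n_meth) / sum(s$n_total)
      } else mean(s$n_meth / s$n_total)
    }
  }
  out[]
}

#' Per-gene CDS methylation for a whole genome
#'
#' Vectorized equivalent of calling [region_methylation()] on every gene's
#' CDS: sites are assigned to genes by CDS overlap and read counts are
#' accumulated per gene and context.
#'
#' @param sites Site table for one genome.
#' @param models A [gene_models()] object, or a data.frame of CDS intervals
#'   with columns `gene_id`, `chrom`, `start`, `end`.
#' @param method `"weighted"` or `"site_mean"` as in [region_methylation()].
#' @return data.table with one row per gene: `gene_id`, `mCG`, `mCHG`,
#'   `mCHH`, `n_sites_CG`, `n_sites_CHG`, `n_sites_CHH`. Genes with no
#'   covered sites in a context get NA level and count 0.
#' @export
genome_methylation <- function(sites, models, method = c("weighted", "site_mean")) {
  method <- match.arg(method)
  cds <- if (inherits(models, "gene_models")) models$cds else as.data.table(models)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(cds)))
  gene_ids <- unique(cds$gene_id)
  # merge per-gene overlapping CDS pieces so sites are not double counted
  # (single grouped reduce, vectorized across all genes)
  key <- paste(cds$gene_id, cds$chrom, sep = "\r")
  red <- IRanges::reduce(S4Vectors::split(
    IRanges::IRanges(cds$start + 1L, cds$end), key))
  rd <- as.data.table(as.data.frame(red))
  r <- data.table(gene_id = sub("\r.*", "", rd$group_name),
                  chrom = sub(".*\r", "", rd$group_name),
                  s = rd$start - 1L, e = rd$end)
  sites <- as.data.table(sites)[n_total >= 1L]
  setkey(r, chrom, s, e)
  q <- sites[, .(chrom, s = pos - 1L, e = as.integer(pos), context,
                 n_meth, n_total)]
  ov <- foverlaps(q, r, type = "within", nomatch = NULL)
  agg <- ov[, .(n = .N, meth = sum(n_meth), tot = sum(n_total),
                site_mean = mean(n_meth / n_total)),
            by = .(gene_id, context)]
  agg[, lev := if (method == "weighted") meth / tot else site_mean]
  out <- data.table(gene_id = gene_ids)
  for (ctx in VALID_CONTEXTS) {
    a <- agg[context == ctx]
    out[[paste0("m", ctx)]] <- a$lev[match(out$gene_id, a$gene_id)]
    n <- a$n[match(out$gene_id, a$gene_id)]
    out[[paste0("n_sites_", ctx)]] <- fifelse(is.na(n), 0L, n)
  }
  out[]
}

#' Strand-aware metagene methylation profile
#'
#' Averages methylation in fixed-width bins around gene landmarks: bins
#' upstream of the TSS, internal bins downstream of the TSS, internal bins
#' upstream of the polyadenylation site, and bins downstream of the polyA
#' site. Minus-strand genes are flipped so that "upstream" is always 5' of
#' the TSS in transcript orientation. Within a gene and bin the level is
#' read-weighted over covered sites (total reads >= 1); across genes each
#' bin is the unweighted mean over genes with a defined bin value.
#'
#' @param models A [gene_models()] object (every gene needs strand and span).
#' @param sites Site table for the same genome.
#' @param upstream_bp Flank width on each side (default 3000).
#' @param internal_bp Internal window anchored at each end of the gene
#'   (default 1500; some published displays use 2000).
#' @param bin Bin width in bp (default 100).
#' @return data.table with columns `context`, `window` (one of `upstream`,
#'   `genic5`, `genic3`, `downstream`), `bin_index` (bins are ordered 5' to
#'   3' along the transcript within each window, so the last `upstream` bin
#'   and the first `downstream` bin are the ones adjacent to the TSS and
#'   polyA respectively), `mean_level` (NA when no gene contributes), and
#'   `n_genes` (number of contributing genes).
#' @export
metagene_profile <- function(models, sites, upstream_bp = 3000L,
                             internal_bp = 1500L, bin = 100L) {
  g <- models$genes
  if (nrow(g) == 0L) stop("no genes")
  n_up <- as.integer(upstream_bp / bin)
  n_in <- as.integer(internal_bp / bin)

  r <- g[, .(gene_id, strand, chrom, gstart = start, gend = end,
             s = start - as.integer(upstream_bp),
             e = end + as.integer(upstream_bp))]
  setkey(r, chrom, s, e)
  sites <- as.data.table(sites)[n_total >= 1L]
  q <- sites[, .(chrom, s = pos - 1L, e = as.integer(pos), context,
                 n_meth, n_total)]
  ov <- foverlaps(q, r, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) stop("no covered sites near any gene")
  ov[, pos0 := i.s]   # site 0-based position (query columns get "i." prefix)
  ov[, glen := gend - gstart]
  ov[, offset5 := fifelse(strand == "+", pos0 - gstart, gend - 1L - pos0)]
  ov[, dist3 := fifelse(strand == "+", gend - 1L - pos0, pos0 - gstart)]

  pieces <- list(
    ov[offset5 < 0L & offset5 >= -upstream_bp,
       .(gene_id, context, n_meth, n_total, win = "upstream",
         bin = n_up + (offset5 %/% as.integer(bin)) + 1L)],
    ov[offset5 >= 0L & offset5 < internal_bp & offset5 < glen,
       .(gene_id, context, n_meth, n_total, win = "genic5",
         bin = (offset5 %/% as.integer(bin)) + 1L)],
    ov[dist3 >= 0L & dist3 < internal_bp & dist3 < glen,
       .(gene_id, context, n_meth, n_total, win = "genic3",
         bin = n_in - (dist3 %/% as.integer(bin)))],
    ov[dist3 < 0L & dist3 >= -upstream_bp,
       .(gene_id, context, n_meth, n_total, win = "downstream",
         bin = -(dist3 %/% as.integer(bin)))]
  )
  hits <- rbindlist(pieces)
  per_gene <- hits[, .(wlevel = sum(n_meth) / sum(n_total)),
                   by = .(context, win, bin, gene_id)]
  prof <- per_gene[, .(mean_level = mean(wlevel), n_genes = .N),
                   by = .(context, win, bin)]

  scaffold <- rbindlist(lapply(VALID_CONTEXTS, function(ctx) rbindlist(list(
    data.table(context = ctx, win = "upstream", bin = seq_len(n_up)),
    data.table(context = ctx, win = "genic5", bin = seq_len(n_in)),
    data.table(context = ctx, win = "genic3", bin = seq_len(n_in)),
    data.table(context = ctx, win = "downstream", bin = seq_len(n_up))
  ))))
  out <- prof[scaffold, on = c("context", "win", "bin")]
  out[is.na(n_genes), n_genes := 0L]
  setnames(out, c("win", "bin"), c("window", "bin_index"))
  out[, window := factor(window, levels = c("upstream", "genic5", "genic3",
                                            "downstream"))]
  setorder(out, context, window, bin_index)
  out[]
}
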