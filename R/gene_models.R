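#' Gene model collection
#'
#' Container for canonical gene models. All coordinates are 0-based
#' half-open; conversion to and from the 1-based closed GFF3 convention
#' happens only at parse/write boundaries.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (transcribed span, 0-based half-open).
#' @param cds,exons,utr5,utr3 data.frames with columns `gene_id`, `chrom`,
#'   `start`, `end`. `utr5`/`utr3` may be empty.
#' @return An object of class `gene_models`: a list of data.tables
#'   (`genes`, `cds`, `exons`, `utr5`, `utr3`). The `genes` table carries
#'   derived `tss` and `polyA` columns (0-based positions of the first and
#'   last transcribed base in transcript orientation).
#' @export
gene_models <- function(genes, cds, exons = cds, utr5 = NULL, utr3 = NULL) {
  genes <- as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(genes$strand %in% c("+", "-")),
            !anyDuplicated(genes$gene_id))
  iv <- function(x) {
    if (is.null(x)) return(data.table(gene_id = character(), chrom = character(),
                                      start = integer(), end = integer()))
    x <- as.data.table(x)[, .(gene_id, chrom, start = as.integer(start),
                              end = as.integer(end))]
    if (any(x$end < x$start)) stop("interval with negative length")
    x
  }
  genes[, `:=`(start = as.integer(start), end = as.integer(end))]
  genes[, tss := fifelse(strand == "+", start, end - 1L)]
  genes[, polyA := fifelse(strand == "+", end - 1L, start)]
  structure(list(genes = genes, cds = iv(cds), exons = iv(exons),
                 utr5 = iv(utr5), utr3 = iv(utr3)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "sequence(s);",
      nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

#' Read canonical gene models from a GFF3 file
#'
#' Imports a GFF3 annotation and keeps one (canonical) transcript per gene.
#' When `canonical_attribute` is present on mRNA records its value selects
#' the canonical transcript; otherwise the first transcript of each gene is
#' used.
#'
#' @param path GFF3 file path.
#' @param canonical_attribute Name of the mRNA attribute that flags the
#'   canonical transcript (records where it equals `"1"`, `"true"` or
#'   `"yes"`).
#' @return A [gene_models()] object (0-based half-open coordinates).
#' @export
read_gene_models <- function(path, canonical_attribute = "canonical_transcript") {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  get1 <- function(x) vapply(x, function(v) if (length(v)) v[[1]] else NA_character_, "")
  parent <- if ("Parent" %in% names(md)) get1(md$Parent) else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))

  mrna <- which(typ %in% c("mRNA", "transcript"))
  if (!length(mrna)) stop("no mRNA/transcript records in ", path)
  mr <- data.table(tx_id = id[mrna], gene_id = parent[mrna], idx = mrna)
  if (canonical_attribute %in% names(md)) {
    flag <- tolower(as.character(get1(md[[canonical_attribute]])[mrna]))
    mr[, canon := flag %in% c("1", "true", "yes")]
    mr <- mr[order(-canon)]
  }
  mr <- mr[!duplicated(gene_id)]

  keep_tx <- setNames(mr$gene_id, mr$tx_id)
  child <- data.table(
    type = typ, tx = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr)
  )
  child <- child[tx %in% names(keep_tx)]
  child[, gene_id := keep_tx[tx]]
  pick <- function(types) child[type %in% types, .(gene_id, chrom, start, end)]

  gn <- data.table(
    gene_id = mr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr))[mr$idx],
    strand = as.character(GenomicRanges::strand(gr))[mr$idx],
    start = GenomicRanges::start(gr)[mr$idx] - 1L,
    end = GenomicRanges::end(gr)[mr$idx]
  )
  gene_models(gn,
              cds = pick("CDS"),
              exons = pick("exon"),
              utr5 = pick("five_prime_UTR"),
              utr3 = pick("three_prime_UTR"))
}

#' Write gene models as GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, start, end, strand, attrs) {
    # internal 0-based half-open -> GFF3 1-based closed
    paste(chrom, "epipangene", type, start + 1L, end, ".", strand, ".",
          attrs, sep = "\t")
  }
  tx_id <- paste0(g$gene_id, "_T001")
  lines <- c(lines,
             fmt(g$chrom, "gene", g$start, g$end, g$strand,
                 paste0("ID=", g$gene_id)),
             fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
                 paste0("ID=", tx_id, ";Parent=", g$gene_id,
                        ";canonical_transcript=1")))
  strand_of <- setNames(g$strand, g$gene_id)
  emit <- function(tab, type) {
    if (nrow(tab) == 0L) return(character())
    fmt(tab$chrom, type, tab$start, tab$end, strand_of[tab$gene_id],
        paste0("Parent=", tab$gene_id, "_T001"))
  }
  lines <- c(lines,
             emit(models$exons, "exon"),
             emit(models$cds, "CDS"),
             emit(models$utr5, "five_prime_UTR"),
             emit(models$utr3, "three_prime_UTR"))
  writeLines(lines, path)
  invisible(path)
}

#' Derive intron intervals from exons
#'
#' Gene annotations typically lack intron records; introns are the gaps
#' between consecutive exons of the canonical transcript.
#'
#' @param exons data.frame of exon intervals for one gene (`start`, `end`,
#'   0-based half-open; a `chrom` column is carried through if present).
#' @return data.table of intron intervals (possibly zero rows).
#' @export
derive_introns <- function(exons) {
  ex <- as.data.table(exons)
  if (nrow(ex) <= 1L) {
    out <- ex[0L]
    return(out[, .(start, end)])
  }
  setorder(ex, start)
  if (any(ex$start[-1L] < ex$end[-nrow(ex)])) stop("overlapping exons")
  data.table(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}
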