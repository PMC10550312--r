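#' @importFrom data.table data.table as.data.table fread fwrite setnames
#'   setkey setkeyv foverlaps rbindlist setDT copy setorder setcolorder
#'   fifelse :=
#' @importFrom stats median sd cor setNames
#' @importFrom utils head tail
NULL

# data.table NSE columns, declared so R CMD check stays quiet
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "chrom", "pos", "pos0", "context", "subcontext",
  "level", "n_meth", "n_total", "start", "end", "gene_id", "strand", "win",
  "bin", "offset5", "dist3", "gstart", "gend", "glen", "mean_level",
  "n_genes", "i.start", "i.end", "i.s", "i.e", "s", "e", "keep", "label",
  "mCG", "mCHG", "mCHH", "n_sites_CG", "n_sites_CHG", "n_sites_CHH",
  "wlevel", "tss", "polyA", "tx", "tx_id", "canon", "type", "idx", "cell",
  "cell_type", "pangene_id", "genome", "n_in_cell", "singleton_cell",
  "median_len", "cds_len", "n_intact", "epi", "core", "excluded", "class",
  "subtype", "subtype_all", "singleton_type", "singleton_epiallele",
  "stratum", "dup_epiallele", "n", "N", "lev", "meth", "tot", "site_mean",
  "superfamily", "exon_count", "has_utr", "intron_te_len_total",
  "cds_te_overlap_len", "te_superfamilies_in_introns", "has_cds_te_ge100",
  "synteny_sorghum", "utr_len_total", "exon_len_total", "intron_len_total",
  "category", "fraction", "copy", "is_dup", "true_type", "partial",
  "base_type", "g", "w", "frac", "len", "intron", "cum_intron", "cum_cds",
  "piece_start", "piece_end", "cum_start", "cum_end", "o1", "o2", "k",
  "offset", "side", "mu", "p", "te_len", "te_start", "te_end", "olap",
  "true_rate", "true_delta_pct", "normalized_median_pct", "sign_test_p",
  "wilcoxon_p", "tissue", "V1", "mult", "true_class", "off",
  "n_singleton_cells", "n_dup_cells", "n_defined_singletons",
  "n_singleton_types", "n_types", "min_type_count", "n_defined", "out_cell"
))

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read per-cytosine methylation records in CGmap format
#'
#' Reads the 8-column tab-delimited CGmap dialect: chromosome, nucleotide on
#' the reported strand, 1-based position, context class (CG/CHG/CHH),
#' sub-context, methylation level, methylated read count, total read count.
#' Optionally restricts records to a set of genomic regions (e.g. coding
#' sequence), mirroring a select-region step before computing per-gene
#' methylation.
#'
#' @param path Path to a CGmap file. Files ending in `.gz` are decompressed
#'   on the fly.
#' @param regions Optional region set used to filter records: a data.frame
#'   with columns `chrom`, `start`, `end` in 0-based half-open coordinates.
#'   A record at 1-based position `p` is kept when `p - 1` falls inside a
#'   region on the same chromosome.
#' @param on_error How to handle malformed lines: `"warn"` (default) drops
#'   them, reports each with its line number, and records them in the
#'   `"errors"` attribute of the result; `"stop"` raises an error naming the
#'   first offending line.
#' @return A `data.table` with columns `chrom`, `strand_base`, `pos`
#'   (1-based), `context`, `subcontext`, `level`, `n_meth`, `n_total`.
#'   Malformed-line reports are attached as attribute `"errors"` (a
#'   data.frame with columns `line` and `reason`).
#' @export
read_cgmap <- function(path, regions = NULL, on_error = c("warn", "stop")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("CGmap file not found: ", path)
  if (grepl("\\.gz$", path)) {
    txt <- readLines(gzfile(path))
    dt <- if (length(txt)) {
      fread(text = txt, header = FALSE, sep = "\t",
            colClasses = "character", fill = TRUE)
    } else data.table()
  } else {
    dt <- fread(path, header = FALSE, sep = "\t",
                colClasses = "character", fill = TRUE)
  }
  if (nrow(dt) == 0L) {
    out <- empty_sites()
    attr(out, "errors") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  if (ncol(dt) < 8L) for (j in seq.int(ncol(dt) + 1L, 8L)) dt[[paste0("V", j)]] <- NA_character_
  setnames(dt, seq_len(8L)[seq_len(min(8L, ncol(dt)))],
           c("chrom", "strand_base", "pos", "context", "subcontext",
             "level", "n_meth", "n_total")[seq_len(min(8L, ncol(dt)))])

  pos <- suppressWarnings(as.integer(dt$pos))
  level <- suppressWarnings(as.numeric(dt$level))
  n_meth <- suppressWarnings(as.integer(dt$n_meth))
  n_total <- suppressWarnings(as.integer(dt$n_total))

  reason <- rep(NA_character_, nrow(dt))
  bad_ctx <- !(dt$context %in% VALID_CONTEXTS)
  reason[bad_ctx] <- paste0("unknown context token '", dt$context[bad_ctx], "'")
  bad_num <- is.na(pos) | is.na(level) | is.na(n_meth) | is.na(n_total)
  reason[bad_num & is.na(reason)] <- "non-numeric or missing field"
  bad_cnt <- !is.na(n_meth) & !is.na(n_total) & (n_meth > n_total | n_total < 1L)
  reason[bad_cnt & is.na(reason)] <- "methylated count exceeds total or total < 1"

  bad <- which(!is.na(reason))
  errors <- data.frame(line = bad, reason = reason[bad],
                       stringsAsFactors = FALSE)
  if (length(bad)) {
    msg <- paste0("line ", errors$line, ": ", errors$reason, collapse = "; ")
    if (on_error == "stop") stop("malformed CGmap record(s): ", msg)
    warning("dropped ", length(bad), " malformed CGmap record(s): ", msg)
  }

  keep_row <- is.na(reason)
  out <- data.table(
    chrom = dt$chrom[keep_row],
    strand_base = dt$strand_base[keep_row],
    pos = pos[keep_row],
    context = dt$context[keep_row],
    subcontext = dt$subcontext[keep_row],
    level = level[keep_row],
    n_meth = n_meth[keep_row],
    n_total = n_total[keep_row]
  )
  if (!is.null(regions)) out <- filter_sites(out, regions)
  attr(out, "errors") <- errors
  out[]
}

empty_sites <- function() {
  data.table(chrom = character(), strand_base = character(), pos = integer(),
             context = character(), subcontext = character(),
             level = numeric(), n_meth = integer(), n_total = integer())
}

#' Write per-cytosine methylation records as CGmap text
#'
#' @param sites A site table as returned by [read_cgmap()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(sites, path) {
  sites <- as.data.table(sites)
  out <- sites[, .(chrom, strand_base, pos, context, subcontext,
                   level = formatC(level, format = "fg", digits = 4),
                   n_meth, n_total)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Restrict site records to a region set
#'
#' @param sites Site table (1-based `pos`).
#' @param regions data.frame with `chrom`, `start`, `end`, 0-based half-open.
#' @return The subset of `sites` whose positions fall inside a region,
#'   in the original order.
#' @export
filter_sites <- function(sites, regions) {
  sites <- as.data.table(sites)
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L) return(sites[0L])
  if (nrow(sites) == 0L) return(sites)
  q <- data.table(chrom = sites$chrom, s = sites$pos - 1L, e = sites$pos,
                  idx = seq_len(nrow(sites)))
  r <- regions[, .(chrom, s = as.integer(start), e = as.integer(end))]
  setkey(r, chrom, s, e)
  hit <- foverlaps(q, r, type = "within", nomatch = NULL, which = TRUE)
  sites[sort(unique(q$idx[hit$xid]))]
}

merge_intervals <- function(iv) {
  # iv: data.table with start, end (0-based half-open); merges overlaps/abutting
  iv <- as.data.table(iv)
  if (nrow(iv) == 0L) return(iv)
  has_chrom <- "chrom" %in% names(iv)
  if (!has_chrom) iv <- copy(iv)[, chrom := "."]
  ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  red <- S4Vectors::split(ir, iv$chrom)
  red <- IRanges::reduce(red)
  out <- rbindlist(lapply(names(red), function(ch) {
    r <- red[[ch]]
    data.table(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }))
  if (!has_chrom) out[, chrom := NULL]
  out[]
}
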