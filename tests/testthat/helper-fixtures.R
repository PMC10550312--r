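# shared fixtures and independent brute-force oracles

make_sites <- function(pos, context = "CG", n_meth = 1L, n_total = 2L,
                       chrom = "chr1") {
  k <- length(pos)
  data.table::data.table(
    chrom = rep_len(chrom, k), strand_base = "C", pos = as.integer(pos),
    context = rep_len(context, k),
    subcontext = rep_len(c(CG = "CG", CHG = "CA", CHH = "CC")[context], k),
    level = rep_len(n_meth, k) / rep_len(n_total, k),
    n_meth = as.integer(rep_len(n_meth, k)),
    n_total = as.integer(rep_len(n_total, k)))
}

write_cgmap_lines <- function(lines, path = tempfile(fileext = ".cgmap")) {
  writeLines(lines, path)
  path
}

# single-gene model helper
one_gene_model <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = 10000L, end = 12000L, cds = NULL,
                           exons = NULL, utr5 = NULL, utr3 = NULL) {
  if (is.null(cds)) cds <- data.frame(gene_id = gene_id, chrom = chrom,
                                      start = start, end = end)
  if (is.null(exons)) exons <- cds
  gene_models(data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = start, end = end),
              cds = cds, exons = exons, utr5 = utr5, utr3 = utr3)
}

# brute-force per-site accumulation of region methylation
oracle_region_methylation <- function(sites, regions) {
  out <- list(mCG = NA_real_, mCHG = NA_real_, mCHH = NA_real_,
              n_CG = 0L, n_CHG = 0L, n_CHH = 0L)
  for (ctx in c("CG", "CHG", "CHH")) {
    meth <- 0L; tot <- 0L; n <- 0L
    seen <- character()
    for (i in seq_len(nrow(sites))) {
      if (sites$context[i] != ctx || sites$n_total[i] < 1) next
      p0 <- sites$pos[i] - 1L
      inside <- FALSE
      for (j in seq_len(nrow(regions))) {
        if (sites$chrom[i] == regions$chrom[j] &&
            p0 >= regions$start[j] && p0 < regions$end[j]) inside <- TRUE
      }
      key <- paste(sites$chrom[i], sites$pos[i])
      if (inside && !key %in% seen) {
        seen <- c(seen, key)
        meth <- meth + sites$n_meth[i]
        tot <- tot + sites$n_total[i]
        n <- n + 1L
      }
    }
    out[[paste0("m", ctx)]] <- if (tot > 0) meth / tot else NA_real_
    out[[paste0("n_", ctx)]] <- n
  }
  out
}

# per-base-pair counting oracle for merged interval intersection
oracle_overlap_length <- function(a, b, lim = 10000L) {
  cov_a <- logical(lim); cov_b <- logical(lim)
  for (i in seq_len(nrow(a))) {
    if (a$end[i] > a$start[i]) cov_a[(a$start[i] + 1L):a$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(b))) {
    if (b$end[i] > b$start[i]) cov_b[(b$start[i] + 1L):b$end[i]] <- TRUE
  }
  sum(cov_a & cov_b)
}

# explicit double-loop oracle for per-pangene mean TPM of one type
oracle_mean_tpm <- function(DT, DE, e) {
  out <- numeric(nrow(DT))
  for (i in seq_len(nrow(DT))) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(DT))) {
      if (!is.na(DE[i, j]) && DE[i, j] == e && !is.na(DT[i, j])) {
        num <- num + DT[i, j]; den <- den + 1
      }
    }
    out[i] <- if (den > 0) num / den else NA_real_
  }
  out
}

# literal restatement of the pangene classification rules, used as an
# enumeration oracle; cells: list of character epiallele vectors (one per
# genome; length > 1 = intact tandem duplicates, NULL = no usable gene,
# NA entries = undefined epiallele)
oracle_classify <- function(cells) {
  counts <- vapply(cells, length, 0L)
  sing <- which(counts == 1L)
  dup <- which(counts >= 2L)
  sing_epi <- unlist(lapply(cells[sing], identity))
  sing_def <- sing_epi[!is.na(sing_epi)]
  all_epi <- unlist(cells)
  all_def <- all_epi[!is.na(all_epi)]
  if (length(dup) >= 1L) {
    if (length(sing) >= 2L && length(sing_def) >= 2L &&
        length(unique(sing_def)) == 1L) return("one_to_N")
    return("other")
  }
  types <- unique(all_def)
  if (length(all_def) >= 2L && length(types) == 1L) return("stable_1to1")
  if (length(types) >= 2L && all(table(all_def) >= 2L)) return("unstable_1to1")
  "other"
}

# build a pangene_table + intact filter + epiallele vector from a list of
# per-genome cells (as in oracle_classify), all intact with equal lengths
toy_pangene <- function(cells, pangene_id = "PG1") {
  genomes <- sprintf("G%02d", seq_along(cells))
  gene_ids <- list()
  cell_str <- character(length(cells))
  epi <- character()
  for (j in seq_along(cells)) {
    v <- cells[[j]]
    # NULL = homologous DNA without usable genes: a coordinates-only cell
    # (present for core status, contributes no genes)
    if (is.null(v) || length(v) == 0L) { cell_str[j] <- "chr1:100-200"; next }
    ids <- sprintf("%s_%s_%d", genomes[j], pangene_id, seq_along(v))
    cell_str[j] <- paste(ids, collapse = ";")
    epi[ids] <- ifelse(is.na(v), "undetermined", v)
  }
  wide <- as.data.frame(c(list(pangene_id = pangene_id),
                          setNames(as.list(cell_str), genomes)))
  pt <- pangene_table(wide)
  lens <- setNames(rep(1000, length(epi)), names(epi))
  list(pt = pt, intact = intact_filter(pt, lens), epi = epi)
}
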