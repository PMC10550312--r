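COORD_CELL_RE <- "^[A-Za-z0-9_.]+:[0-9]+-[0-9]+$"

#' Parse a pangene table
#'
#' A pangene table has one row per pangene and one column per genome. Each
#' cell is `"NA"`/empty (missing gene), a coordinate placeholder of the form
#' `chrom:start-end` (homologous DNA present but no annotated gene), a
#' single gene ID, or several gene IDs separated by a sub-delimiter
#' (tandem duplicates).
#'
#' @param wide data.frame whose first column is the pangene ID and remaining
#'   columns are genomes, or a file path to a comma-delimited table.
#' @param sub_delim Separator between gene IDs within a cell (default ";").
#' @return Object of class `pangene_table`: list with `long` (data.table
#'   `pangene_id`, `genome`, `gene_id`, `cell_type` in
#'   missing/coord/gene), `genomes`, `pangene_ids`, `sub_delim`.
#' @export
pangene_table <- function(wide, sub_delim = ";") {
  if (is.character(wide) && length(wide) == 1L) {
    wide <- fread(wide, header = TRUE, colClasses = "character",
                  na.strings = c("NA", ""))
  }
  wide <- as.data.table(wide)
  stopifnot(ncol(wide) >= 2L)
  pid <- as.character(wide[[1L]])
  if (anyDuplicated(pid)) stop("duplicate pangene IDs")
  genomes <- names(wide)[-1L]
  long <- data.table(
    pangene_id = rep(pid, times = length(genomes)),
    genome = rep(genomes, each = length(pid)),
    cell = as.character(unlist(wide[, -1L, with = FALSE], use.names = FALSE))
  )
  long[, cell_type := fifelse(is.na(cell) | cell == "NA", "missing",
                              fifelse(grepl(COORD_CELL_RE, cell), "coord",
                                      "gene"))]
  genes <- long[cell_type == "gene",
                .(gene_id = strsplit(cell, sub_delim, fixed = TRUE)[[1L]]),
                by = .(pangene_id, genome)]
  genes[, `:=`(cell_type = "gene", cell = NA_character_)]
  # keep the original text of coordinate cells so tables round-trip
  other <- long[cell_type != "gene",
                .(pangene_id, genome, gene_id = NA_character_, cell_type,
                  cell = fifelse(cell_type == "coord", cell, NA_character_))]
  out <- rbind(genes, other)
  setorder(out, pangene_id, genome)
  structure(list(long = out, genomes = genomes, pangene_ids = pid,
                 sub_delim = sub_delim),
            class = "pangene_table")
}

#' @export
print.pangene_table <- function(x, ...) {
  cat("pangene_table:", length(x$pangene_ids), "pangenes x",
      length(x$genomes), "genomes;",
      sum(x$long$cell_type == "gene"), "genes\n")
  invisible(x)
}

#' Write a pangene table as comma-delimited text
#'
#' @param pt A [pangene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pangene_table <- function(pt, path) {
  long <- copy(pt$long)
  long[, out_cell := fifelse(cell_type == "gene", gene_id,
                             fifelse(cell_type == "coord", cell,
                                     NA_character_))]
  cells <- long[, .(cell = if (all(cell_type == "missing")) NA_character_
                    else paste(out_cell, collapse = pt$sub_delim)),
                by = .(pangene_id, genome)]
  wide <- data.table::dcast(cells, pangene_id ~ genome, value.var = "cell")
  setcolorder(wide, c("pangene_id", pt$genomes))
  wide <- wide[match(pt$pangene_ids, pangene_id)]
  fwrite(wide, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

#' Identify core pangenes
#'
#' A pangene is core when it is present in every genome. Coordinate-only
#' cells (homologous DNA without a gene annotation) count as present for
#' core status even though they contribute no genes to downstream analyses.
#'
#' @param pt A [pangene_table()].
#' @return data.table `pangene_id`, `core` (logical).
#' @export
core_filter <- function(pt) {
  pres <- pt$long[cell_type != "missing",
                  .(n_present = data.table::uniqueN(genome)), by = pangene_id]
  out <- data.table(pangene_id = pt$pangene_ids)
  np <- pres$n_present[match(out$pangene_id, pres$pangene_id)]
  out[, core := !is.na(np) & np == length(pt$genomes)]
  out[]
}

#' Flag intact genes by CDS-length agreement within each pangene
#'
#' Annotation artifacts and genes with large structural changes are
#' excluded by requiring the cumulative CDS length of each gene to vary by
#' less than 10% from the per-pangene median. Only singleton genes (cells
#' with exactly one gene) contribute to the median; both singletons and
#' tandem duplicates are then compared to it. Pangenes with no singleton
#' are flagged excluded from pangene analyses. Dropping a gene does not
#' change core status.
#'
#' @param pt A [pangene_table()].
#' @param cds_lengths Named numeric vector: cumulative CDS length (bp) per
#'   gene ID. Every gene in the table must be present.
#' @param max_dev Maximum allowed relative deviation (default 0.10,
#'   strictly less than).
#' @return List with `genes` (data.table `pangene_id`, `genome`, `gene_id`,
#'   `cds_len`, `singleton_cell`, `keep`), `median_len` (per pangene), and
#'   `excluded` (pangene IDs with no singleton to define a median).
#' @export
intact_filter <- function(pt, cds_lengths, max_dev = 0.10) {
  g <- pt$long[cell_type == "gene", .(pangene_id, genome, gene_id)]
  miss <- setdiff(g$gene_id, names(cds_lengths))
  if (length(miss)) stop("missing CDS length for gene(s): ",
                         paste(head(miss, 5L), collapse = ", "))
  g[, cds_len := as.numeric(cds_lengths[gene_id])]
  g[, n_in_cell := .N, by = .(pangene_id, genome)]
  g[, singleton_cell := n_in_cell == 1L]
  med <- g[singleton_cell == TRUE, .(median_len = median(cds_len)),
           by = pangene_id]
  g[, median_len := med$median_len[match(pangene_id, med$pangene_id)]]
  g[, keep := !is.na(median_len) & abs(cds_len - median_len) / median_len < max_dev]
  excluded <- setdiff(unique(g$pangene_id), med$pangene_id)
  list(genes = g[, .(pangene_id, genome, gene_id, cds_len, singleton_cell, keep)],
       median_len = med[], excluded = excluded)
}

PANGENE_CLASSES <- c("one_to_N", "stable_1to1", "unstable_1to1", "other")

#' Classify pangene stability and tandem-duplication behavior
#'
#' Operates on core pangenes after the intact-CDS filter. Singleton versus
#' duplicate status of a cell is decided from its intact gene count, so
#' partial duplications are ignored. Labels:
#' \describe{
#'   \item{one_to_N}{at least one genome holds intact tandem duplicates,
#'     at least 2 genomes hold intact singletons, at least 2 singleton
#'     genes have a defined epiallele, and all defined singleton epialleles
#'     are a single type (recorded as `singleton_epiallele`).}
#'   \item{stable_1to1}{only singletons, at least 2 genes with defined
#'     epialleles, all of one type.}
#'   \item{unstable_1to1}{only singletons, at least 2 epiallele types, and
#'     every type present is represented by at least 2 genes; `subtype`
#'     records the combination (e.g. `UM-gbM`).}
#'   \item{other}{everything else.}
#' }
#' Undetermined and low-coverage calls count as "no defined epiallele" and
#' are neutral: they neither qualify nor disqualify a type-uniformity test.
#'
#' @param pt A [pangene_table()].
#' @param intact Result of [intact_filter()].
#' @param epialleles Named character vector (or factor) of epiallele labels
#'   per gene ID; genes absent from it are treated as undefined.
#' @param core Optional result of [core_filter()] (computed when NULL).
#' @return data.table: `pangene_id`, `core`, `excluded`, `class` (NA for
#'   non-core or excluded pangenes), `subtype`, `singleton_epiallele`,
#'   plus singleton/duplicate bookkeeping counts.
#' @export
classify_pangenes <- function(pt, intact, epialleles, core = NULL) {
  if (is.null(core)) core <- core_filter(pt)
  epialleles <- setNames(as.character(epialleles), names(epialleles))
  g <- intact$genes[keep == TRUE]
  g[, n_intact := .N, by = .(pangene_id, genome)]
  g[, epi := epialleles[gene_id]]
  g[, epi := fifelse(epi %in% DEFINED_EPIALLELES, epi, NA_character_)]

  per <- g[, {
    sing <- n_intact == 1L
    se <- epi[sing]
    sdef <- se[!is.na(se)]
    types <- unique(sdef)
    all_e <- epi[!is.na(epi)]
    all_types <- unique(all_e)
    .(n_singleton_cells = sum(sing),
      n_dup_cells = data.table::uniqueN(genome[!sing]),
      n_defined_singletons = length(sdef),
      n_singleton_types = length(types),
      singleton_type = if (length(types) == 1L) types else NA_character_,
      n_types = length(all_types),
      min_type_count = if (length(all_types)) min(table(all_e)) else 0L,
      n_defined = length(all_e),
      subtype_all = if (length(all_types))
        paste(DEFINED_EPIALLELES[DEFINED_EPIALLELES %in% all_types],
              collapse = "-") else NA_character_)
  }, by = pangene_id]

  out <- data.table(pangene_id = pt$pangene_ids)
  out[, core := core$core[match(pangene_id, core$pangene_id)]]
  out[, excluded := pangene_id %in% intact$excluded]
  idx <- match(out$pangene_id, per$pangene_id)
  for (col in c("n_singleton_cells", "n_dup_cells", "n_defined_singletons",
                "n_singleton_types", "n_types", "min_type_count", "n_defined")) {
    v <- per[[col]][idx]
    out[, (col) := fifelse(is.na(v), 0L, as.integer(v))]
  }
  out[, singleton_type := per$singleton_type[idx]]
  out[, subtype_all := per$subtype_all[idx]]

  out[, class := NA_character_]
  eligible <- out$core & !out$excluded
  is_1toN <- out$n_dup_cells >= 1L & out$n_singleton_cells >= 2L &
    out$n_defined_singletons >= 2L & out$n_singleton_types == 1L
  only_sing <- out$n_dup_cells == 0L
  is_stable <- only_sing & out$n_defined >= 2L & out$n_types == 1L
  is_unstable <- only_sing & out$n_types >= 2L & out$min_type_count >= 2L
  out[eligible, class := "other"]
  out[eligible & is_stable, class := "stable_1to1"]
  out[eligible & is_unstable, class := "unstable_1to1"]
  out[eligible & is_1toN, class := "one_to_N"]
  out[, subtype := fifelse(class == "unstable_1to1", subtype_all, NA_character_)]
  out[, singleton_epiallele := fifelse(class == "one_to_N", singleton_type,
                                fifelse(class == "stable_1to1", subtype_all,
                                        NA_character_))]
  out[, subtype_all := NULL]
  out[, singleton_type := NULL]
  out[]
}

#' Count epialleles among intact tandem duplicates of 1-to-N pangenes
#'
#' For each singleton epiallele type, pools the epiallele labels of intact
#' duplicate genes across qualifying pangenes, stratified by the intact
#' copy number of the duplicate cell (`min2`: at least 2 copies, i.e. all
#' duplicate cells; `min4`: only cells with at least 4 intact copies).
#'
#' @param classes Result of [classify_pangenes()].
#' @param intact Result of [intact_filter()].
#' @param epialleles Named vector of labels per gene ID.
#' @param min_copies Integer vector of copy-number strata (default `c(2, 4)`).
#' @return data.table `singleton_epiallele`, `stratum` (e.g. "min2"),
#'   `dup_epiallele`, `n`. Only duplicates with defined epialleles are
#'   counted.
#' @export
count_duplicate_epialleles <- function(classes, intact, epialleles,
                                       min_copies = c(2L, 4L)) {
  epialleles <- setNames(as.character(epialleles), names(epialleles))
  onen <- as.data.table(classes)[class == "one_to_N",
                                 .(pangene_id, singleton_epiallele)]
  g <- intact$genes[keep == TRUE][onen, on = "pangene_id", nomatch = NULL]
  g[, n_intact := .N, by = .(pangene_id, genome)]
  dups <- g[n_intact >= 2L]
  dups[, epi := epialleles[gene_id]]
  dups <- dups[epi %in% DEFINED_EPIALLELES]
  res <- rbindlist(lapply(as.integer(min_copies), function(mc) {
    d <- dups[n_intact >= mc]
    if (nrow(d) == 0L) {
      return(data.table(singleton_epiallele = character(),
                        stratum = character(), dup_epiallele = character(),
                        n = integer()))
    }
    cnt <- d[, .(n = .N), by = .(singleton_epiallele, dup_epiallele = epi)]
    cnt[, stratum := paste0("min", mc)]
    cnt[, .(singleton_epiallele, stratum, dup_epiallele, n)]
  }))
  grid <- data.table::CJ(singleton_epiallele = DEFINED_EPIALLELES,
                         stratum = paste0("min", as.integer(min_copies)),
                         dup_epiallele = DEFINED_EPIALLELES)
  out <- res[grid, on = c("singleton_epiallele", "stratum", "dup_epiallele")]
  out[is.na(n), n := 0L]
  setorder(out, stratum, singleton_epiallele, dup_epiallele)
  out[]
}

#' Relative tandem-duplication propensity of epiallele types
#'
#' For each epiallele type, divides the number of 1-to-N pangenes whose
#' singletons carry that type by the number of stable 1-to-1 pangenes of
#' the same type; the comparative fold is the UM ratio over the gbM ratio.
#'
#' @param n_1toN Named counts of 1-to-N pangenes per singleton type.
#' @param n_stable Named counts of stable 1-to-1 pangenes per type.
#' @return List with `ratio` (named per type; NA with a warning when a
#'   stable count is zero) and `fold_um_vs_gbm`.
#' @export
relative_duplication_ratio <- function(n_1toN, n_stable) {
  types <- union(names(n_1toN), names(n_stable))
  ratio <- setNames(rep(NA_real_, length(types)), types)
  for (t in types) {
    num <- if (t %in% names(n_1toN)) n_1toN[[t]] else 0
    den <- if (t %in% names(n_stable)) n_stable[[t]] else 0
    if (den == 0) {
      warning("zero stable 1-to-1 count for type ", t, "; ratio undefined")
    } else ratio[[t]] <- num / den
  }
  fold <- if (!is.na(ratio["UM"]) && !is.na(ratio["gbM"]) && ratio[["gbM"]] > 0) {
    ratio[["UM"]] / ratio[["gbM"]]
  } else NA_real_
  list(ratio = ratio, fold_um_vs_gbm = fold)
}
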