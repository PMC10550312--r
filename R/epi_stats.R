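#' Build pangene x genome value matrices from intact singletons
#'
#' Arranges per-gene values (TPM, methylation levels, epiallele labels)
#' into a pangene-by-genome matrix. A cell is filled only when the genome
#' holds exactly one intact gene for that pangene (singleton after the
#' intact-CDS filter); duplicate or empty cells are NA.
#'
#' @param intact Result of [intact_filter()].
#' @param values Named vector of per-gene values (character or numeric).
#' @param pangene_ids,genomes Row and column universes (e.g. from the
#'   [pangene_table()]).
#' @return Matrix with `pangene_ids` rownames and `genomes` colnames.
#' @export
pangene_value_matrix <- function(intact, values, pangene_ids, genomes) {
  g <- intact$genes[keep == TRUE]
  g[, n_intact := .N, by = .(pangene_id, genome)]
  s <- g[n_intact == 1L]
  m <- matrix(if (is.numeric(values)) NA_real_ else NA_character_,
              nrow = length(pangene_ids), ncol = length(genomes),
              dimnames = list(pangene_ids, genomes))
  v <- values[s$gene_id]
  m[cbind(match(s$pangene_id, pangene_ids), match(s$genome, genomes))] <- v
  m
}

#' Per-pangene mean TPM of one epiallele type
#'
#' For each pangene, averages the TPM values of the genomes whose gene
#' carries epiallele `e`: the row-wise indicator form
#' `sum_j DT[i,j] * I_e[i,j] / sum_j I_e[i,j]`, undefined (NA) when no
#' genome has the type.
#'
#' @param DT Numeric pangene x genome TPM matrix (one tissue).
#' @param DE Character pangene x genome epiallele matrix (NA = undefined).
#' @param e Epiallele type: "UM", "gbM" or "teM".
#' @return Named numeric vector of per-pangene means.
#' @export
mean_tpm_per_epiallele <- function(DT, DE, e) {
  if (!identical(dim(DT), dim(DE))) stop("DT and DE shapes differ")
  ind <- !is.na(DE) & DE == e & !is.na(DT)
  num <- rowSums(DT * ind, na.rm = TRUE)
  den <- rowSums(ind)
  out <- num / den
  out[den == 0] <- NA_real_
  setNames(out, rownames(DT))
}

#' Sign and signed-rank tests on paired epiallele expression differences
#'
#' Given per-pangene differences (e.g. mean gbM TPM minus mean UM TPM),
#' performs the exact two-sided binomial sign test on the number of
#' positive differences among non-tied pairs (p = 0.5), and the two-sided
#' Wilcoxon signed-rank test with zeros dropped (exact distribution for up
#' to 25 non-zero differences, normal approximation with tie correction
#' above). The median difference is also reported as a percentage of the
#' mean UM TPM when `mean_um` is supplied.
#'
#' @param d Numeric vector of per-pangene differences (NAs dropped).
#' @param mean_um Mean UM TPM over the same pangene set (for the
#'   normalized median); NA to skip.
#' @param tissue Optional label carried into the result.
#' @return One-row data.table: `tissue`, `n`, `n_pos`, `n_neg`, `n_tie`,
#'   `median_d`, `mean_d`, `normalized_median_pct`, `sign_test_p`,
#'   `sign_test_p_with_ties` (ties counted in the binomial n, reported for
#'   comparison), `wilcoxon_p`.
#' @export
paired_difference_tests <- function(d, mean_um = NA_real_, tissue = NA_character_) {
  d <- d[!is.na(d)]
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  n_tie <- sum(d == 0)
  n_eff <- n_pos + n_neg
  sign_p <- if (n_eff > 0) {
    stats::binom.test(n_pos, n_eff, p = 0.5, alternative = "two.sided")$p.value
  } else NA_real_
  sign_p_ties <- if (length(d) > 0) {
    stats::binom.test(n_pos, length(d), p = 0.5, alternative = "two.sided")$p.value
  } else NA_real_
  dz <- d[d != 0]
  wilcox_p <- if (length(dz) > 0) {
    suppressWarnings(stats::wilcox.test(dz, alternative = "two.sided",
                                        exact = length(dz) <= 25L)$p.value)
  } else NA_real_
  data.table(tissue = tissue, n = length(d), n_pos = n_pos, n_neg = n_neg,
             n_tie = n_tie,
             median_d = if (length(d)) median(d) else NA_real_,
             mean_d = if (length(d)) mean(d) else NA_real_,
             normalized_median_pct = if (length(d) && !is.na(mean_um) &&
                                         mean_um != 0)
               100 * median(d) / mean_um else NA_real_,
             sign_test_p = sign_p, sign_test_p_with_ties = sign_p_ties,
             wilcoxon_p = wilcox_p)
}

#' gbM-UM expression differences per tissue with sign/signed-rank tests
#'
#' Convenience wrapper: computes per-pangene mean TPM for two epiallele
#' types, their paired differences over pangenes where both are defined,
#' and the associated tests, per tissue.
#'
#' @param DT_list Named list of pangene x genome TPM matrices, one per
#'   tissue.
#' @param DE Pangene x genome epiallele matrix.
#' @param type_hi,type_lo The two types compared (difference is hi - lo;
#'   defaults gbM - UM).
#' @return data.table with one row per tissue ([paired_difference_tests()]
#'   columns).
#' @export
epiallele_difference_tests <- function(DT_list, DE, type_hi = "gbM",
                                       type_lo = "UM") {
  rbindlist(lapply(names(DT_list), function(tis) {
    DT <- DT_list[[tis]]
    hi <- mean_tpm_per_epiallele(DT, DE, type_hi)
    lo <- mean_tpm_per_epiallele(DT, DE, type_lo)
    both <- !is.na(hi) & !is.na(lo)
    paired_difference_tests(hi[both] - lo[both],
                            mean_um = mean(lo[both]), tissue = tis)
  }))
}

#' Chi-square test on duplicate epiallele proportions
#'
#' Pearson chi-square without continuity correction comparing epiallele
#' counts between two duplicate strata (e.g. minimum copy number 2 versus
#' 4).
#'
#' @param counts_a,counts_b Named (or aligned) count vectors over epiallele
#'   types, or a 2 x k matrix passed as `counts_a` alone.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
duplicate_proportion_test <- function(counts_a, counts_b = NULL) {
  tab <- if (is.null(counts_b)) as.matrix(counts_a) else rbind(counts_a, counts_b)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need a 2 x k table with k >= 2")
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cnt == 0)) stop("zero expected count in chi-square table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}

#' Per-pangene methylation-expression correlations
#'
#' Pearson correlation between a methylation variable (mCG or mCHG) and
#' TPM across genomes, one coefficient per pangene and tissue. A pangene
#' enters a tissue's summary only when it has at least `min_genes` genomes
#' with both values defined, the spread between its most extreme two
#' methylation values is at least `min_range`, and neither variable has
#' zero standard deviation (the coefficient is NA otherwise). Low
#' confidence genes (CDS-length deviation, insufficient coverage) are
#' expected to be masked to NA in `meth` upstream.
#'
#' @param meth Pangene x genome methylation matrix (levels in \[0, 1\]).
#' @param DT_list Named list of pangene x genome TPM matrices per tissue.
#' @param min_range Minimum max-minus-min methylation spread (default 0.2).
#' @param min_genes Minimum genomes with both values (default 3).
#' @return List with `summary` (per tissue: `tissue`, `n`, `median_r`,
#'   `mean_r`, `n_pos`, `n_neg`, `pos_neg_ratio`) and `r` (pangene x tissue
#'   matrix of coefficients, NA where undefined or excluded).
#' @export
methylation_expression_correlation <- function(meth, DT_list, min_range = 0.2,
                                               min_genes = 3L) {
  tissues <- names(DT_list)
  rmat <- matrix(NA_real_, nrow = nrow(meth), ncol = length(tissues),
                 dimnames = list(rownames(meth), tissues))
  for (tis in tissues) {
    tpm <- DT_list[[tis]]
    ok <- !is.na(meth) & !is.na(tpm)
    n <- rowSums(ok)
    x <- ifelse(ok, meth, NA)
    y <- ifelse(ok, tpm, NA)
    rng <- apply(x, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) max(v) - min(v) else NA_real_
    })
    sx <- apply(x, 1L, sd, na.rm = TRUE)
    sy <- apply(y, 1L, sd, na.rm = TRUE)
    use <- n >= min_genes & !is.na(rng) & rng >= min_range - 1e-9 &
      !is.na(sx) & sx > 0 & !is.na(sy) & sy > 0
    idx <- which(use)
    r <- vapply(idx, function(i) {
      stats::cor(x[i, ], y[i, ], use = "complete.obs")
    }, numeric(1L))
    rmat[idx, tis] <- r
  }
  summary <- rbindlist(lapply(tissues, function(tis) {
    r <- rmat[, tis]
    r <- r[!is.na(r)]
    data.table(tissue = tis, n = length(r),
               median_r = if (length(r)) median(r) else NA_real_,
               mean_r = if (length(r)) mean(r) else NA_real_,
               n_pos = sum(r > 0), n_neg = sum(r < 0),
               pos_neg_ratio = if (sum(r < 0) > 0) sum(r > 0) / sum(r < 0)
               else if (sum(r > 0) > 0) Inf else NA_real_)
  }))
  list(summary = summary, r = rmat)
}
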