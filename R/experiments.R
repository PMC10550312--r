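#' Configuration for the gbM expression-effect recovery experiment
#'
#' A simulated pan-genome composed entirely of unstable UM-gbM 1-to-1
#' pangenes: every pangene is singleton-only with both UM and gbM
#' epialleles represented, so the paired gbM-UM expression comparison has
#' maximal power to recover the injected expression effect.
#'
#' @param n_pangenes Number of pangenes (default 1000).
#' @param n_genomes Number of genomes (default 26).
#' @param delta Injected gbM expression effect (default 0.03).
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
unstable_umgbm_config <- function(n_pangenes = 1000L, n_genomes = 26L,
                                  delta = 0.03, ...) {
  sim_config(n_genomes = n_genomes, n_pangenes = n_pangenes,
             epiallele_freq = c(UM = 0.5, gbM = 0.5, teM = 0),
             singleton_unstable_frac = 1, p_tandem = 0,
             p_noncore = 0, p_coord = 0,
             delta_gbm = delta, ...)
}

# run calling + classification + the paired test for one simulated dataset
run_delta_recovery_once <- function(cfg, tissue, thresholds) {
  sim <- simulate_pangenome(cfg, level = "gene")
  gm <- rbindlist(sim$gene_meth)
  calls <- call_epiallele(gm, thresholds)
  epi <- setNames(as.character(calls$label), calls$gene_id)
  pt <- sim$pangene_table
  intact <- intact_filter(pt, sim$cds_lengths)
  classes <- classify_pangenes(pt, intact, epi)
  um_gbm <- classes[class == "unstable_1to1" & subtype == "UM-gbM", pangene_id]
  DE <- pangene_value_matrix(intact, epi, pt$pangene_ids, pt$genomes)
  DE[!(DE %in% DEFINED_EPIALLELES)] <- NA
  tpm_all <- do.call(rbind, unname(sim$tpm))
  DT <- pangene_value_matrix(intact, setNames(tpm_all[, tissue],
                                              rownames(tpm_all)),
                             pt$pangene_ids, pt$genomes)
  res <- epiallele_difference_tests(list(x = DT[um_gbm, , drop = FALSE]),
                                    DE[um_gbm, , drop = FALSE])
  res[, tissue := tissue]
  res[, n_unstable_umgbm := length(um_gbm)]
  res[]
}

#' Replicated recovery of the injected gbM expression effect
#'
#' Repeatedly simulates an unstable-UM-gbM pan-genome, runs epiallele
#' calling, pangene classification and the paired gbM-UM expression test,
#' and collects the recovered normalized median difference and test
#' p-values per replicate.
#'
#' @param n_reps Number of simulation replicates.
#' @param cfg Generator configuration (default [unstable_umgbm_config()]).
#' @param tissue Tissue analyzed (default `"leaf_tip"`; avoid endosperm,
#'   where the effect is attenuated by design).
#' @param thresholds A [threshold_config()].
#' @return data.table with one row per replicate: `rep`,
#'   `n_unstable_umgbm`, `normalized_median_pct`, `sign_test_p`,
#'   `wilcoxon_p`, `n_pos`, `n_neg`.
#' @export
delta_recovery_replicates <- function(n_reps = 50L,
                                      cfg = unstable_umgbm_config(),
                                      tissue = "leaf_tip",
                                      thresholds = threshold_config()) {
  rbindlist(lapply(seq_len(n_reps), function(r) {
    res <- run_delta_recovery_once(cfg, tissue, thresholds)
    res[, rep := r]
    res[, .(rep, n_unstable_umgbm, normalized_median_pct, sign_test_p,
            wilcoxon_p, n_pos, n_neg)]
  }))
}

#' Null mCG-expression correlation run
#'
#' Simulates a pan-genome with a zero expression effect (`delta_gbm = 0`,
#' so mCG carries no information about expression), builds the masked
#' per-pangene mCG matrix and computes the per-pangene Pearson
#' correlations; under the null their median should sit within sampling
#' error of zero.
#'
#' @param cfg Generator configuration (default [unstable_umgbm_config()]
#'   with `delta = 0`, which guarantees wide mCG spread within pangenes).
#' @param tissue Tissue analyzed.
#' @param thresholds A [threshold_config()].
#' @return List: `median_r`, `se_median` (1.2533 sd/sqrt(n)), `n`,
#'   `summary` (the per-tissue summary row).
#' @export
null_correlation_run <- function(cfg = unstable_umgbm_config(delta = 0),
                                 tissue = "leaf_tip",
                                 thresholds = threshold_config()) {
  sim <- simulate_pangenome(cfg, level = "gene")
  gm <- rbindlist(sim$gene_meth)
  pt <- sim$pangene_table
  intact <- intact_filter(pt, sim$cds_lengths)
  covered <- gm$n_sites_CG >= thresholds$min_sites_CG &
    gm$n_sites_CHG >= thresholds$min_sites_CHG
  mcg <- setNames(gm$mCG, gm$gene_id)
  mcg[!covered | is.na(gm$mCHG) | gm$mCHG > 0.05] <- NA
  MCG <- pangene_value_matrix(intact, mcg, pt$pangene_ids, pt$genomes)
  tpm_all <- do.call(rbind, unname(sim$tpm))
  DT <- pangene_value_matrix(intact, setNames(tpm_all[, tissue],
                                              rownames(tpm_all)),
                             pt$pangene_ids, pt$genomes)
  res <- methylation_expression_correlation(MCG, setNames(list(DT), tissue))
  r <- res$r[, tissue]
  r <- r[!is.na(r)]
  list(median_r = median(r),
       se_median = 1.2533 * sd(r) / sqrt(length(r)),
       n = length(r), summary = res$summary)
}
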