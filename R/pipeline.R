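#' Run the full pan-genome epiallele analysis on simulated input
#'
#' Orchestrates the stages end to end: simulate a pan-genome, compute
#' per-gene CDS methylation for every genome, call epialleles, summarize
#' structural features and expression categories, classify pangenes, count
#' duplicate epialleles, and run the epiallele-expression statistics
#' (paired gbM-UM differences with sign/signed-rank tests, and per-pangene
#' methylation-expression correlations). Each stage logs to `stderr`; a
#' failing stage halts with its name.
#'
#' @param cfg A [sim_config()] describing the simulated dataset.
#' @param thresholds A [threshold_config()] for epiallele calling.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as delimited tables plus a plain-text summary, and the configuration
#'   is serialized alongside for provenance.
#' @param level Simulation detail passed to [simulate_pangenome()]
#'   (`"sites"` exercises the full CGmap path; `"gene"` is faster).
#' @param quiet Suppress progress messages.
#' @return A list of class `pangenome_report`: `sim`, `calls` (combined
#'   per-gene table with genome column), `call_summaries`, `features`,
#'   `metagene`, `expression_categories`, `classes`, `class_counts`,
#'   `dup_counts`, `dup_ratio`, `diff_tests`, `correlation`
#'   (mCG and mCHG variants), `truth_recovery`.
#' @export
run_pipeline <- function(cfg = sim_config(), thresholds = threshold_config(),
                         out_dir = NULL, level = c("sites", "gene"),
                         quiet = FALSE) {
  level <- match.arg(level)
  log_msg <- function(...) if (!quiet) message("[epipangene] ", ...)
  stage <- function(name, expr) {
    log_msg("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_pangenome(cfg, level = level))

  meth <- stage("methylation", {
    if (level == "sites") {
      lapply(setNames(sim$genomes, sim$genomes), function(g) {
        genome_methylation(sim$sites[[g]], sim$models[[g]])
      })
    } else sim$gene_meth
  })

  callres <- stage("call", {
    lapply(setNames(sim$genomes, sim$genomes), function(g) {
      call_genome(meth[[g]], thresholds)
    })
  })
  calls <- rbindlist(lapply(sim$genomes, function(g) {
    copy(callres[[g]]$calls)[, genome := g]
  }))
  call_summaries <- rbindlist(lapply(sim$genomes, function(g) {
    copy(callres[[g]]$summary)[, genome := g]
  }))
  epi_vec <- setNames(as.character(calls$label), calls$gene_id)

  ref_genome <- sim$genomes[[1L]]
  features <- NULL
  metagene <- NULL
  if (level == "sites") {
    features <- stage("features", {
      ft <- feature_table(sim$models[[ref_genome]], te = sim$te[[ref_genome]])
      list(table = ft,
           by_epiallele = feature_summary_by_epiallele(
             ft, callres[[ref_genome]]$calls))
    })
    metagene <- stage("metagene", {
      core_models <- sim$models[[ref_genome]]
      metagene_profile(core_models, sim$sites[[ref_genome]])
    })
  }

  expression_categories <- stage("expression", {
    rbindlist(lapply(sim$genomes, function(g) {
      copy(categorize_expression(sim$tpm[[g]]))[, genome := g]
    }))
  })

  pg <- stage("pangenes", {
    pt <- sim$pangene_table
    core <- core_filter(pt)
    intact <- intact_filter(pt, sim$cds_lengths)
    classes <- classify_pangenes(pt, intact, epi_vec, core = core)
    dup_counts <- count_duplicate_epialleles(classes, intact, epi_vec)
    n_1toN <- table(classes[class == "one_to_N", singleton_epiallele])
    n_stable <- table(classes[class == "stable_1to1", singleton_epiallele])
    ratio <- if (all(c("UM", "gbM") %in% names(n_1toN)) &&
                 all(c("UM", "gbM") %in% names(n_stable))) {
      relative_duplication_ratio(as.list(n_1toN), as.list(n_stable))
    } else NULL
    list(core = core, intact = intact, classes = classes,
         class_counts = classes[, .N, by = class],
         dup_counts = dup_counts, dup_ratio = ratio)
  })

  st <- stage("stats", {
    pt <- sim$pangene_table
    intact <- pg$intact
    DE <- pangene_value_matrix(intact, epi_vec, pt$pangene_ids, pt$genomes)
    DE[!(DE %in% DEFINED_EPIALLELES)] <- NA
    tpm_all <- do.call(rbind, unname(sim$tpm))
    DT_list <- lapply(setNames(cfg$tissues, cfg$tissues), function(tis) {
      pangene_value_matrix(intact, setNames(tpm_all[, tis], rownames(tpm_all)),
                           pt$pangene_ids, pt$genomes)
    })
    # restrict the paired comparison to unstable UM-gbM 1-to-1 pangenes
    um_gbm <- pg$classes[class == "unstable_1to1" & subtype == "UM-gbM",
                         pangene_id]
    DE_u <- DE[um_gbm, , drop = FALSE]
    DT_u <- lapply(DT_list, function(m) m[um_gbm, , drop = FALSE])
    diff_tests <- epiallele_difference_tests(DT_u, DE_u)

    # quantitative mCG-TPM correlation: mask low-confidence genes, drop
    # mCHG-methylated genes to avoid confounding by TE-like methylation
    meth_all <- rbindlist(meth)
    mvec <- function(col) setNames(meth_all[[col]], meth_all$gene_id)
    covered <- meth_all$n_sites_CG >= thresholds$min_sites_CG &
      meth_all$n_sites_CHG >= thresholds$min_sites_CHG
    mcg <- mvec("mCG")
    mchg <- mvec("mCHG")
    mcg[!covered | is.na(mchg) | mchg > 0.05] <- NA
    MCG <- pangene_value_matrix(intact, mcg, pt$pangene_ids, pt$genomes)
    cor_mcg <- methylation_expression_correlation(MCG, DT_list)
    mchg2 <- mvec("mCHG")
    mchg2[!covered] <- NA
    MCHG <- pangene_value_matrix(intact, mchg2, pt$pangene_ids, pt$genomes)
    cor_mchg <- methylation_expression_correlation(MCHG, DT_list)
    list(DE = DE, DT_list = DT_list, diff_tests = diff_tests,
         correlation = list(mCG = cor_mcg, mCHG = cor_mchg))
  })

  truth_recovery <- stage("truth_compare", {
    truth_compare(sim, calls = calls, classes = pg$classes,
                  dup_counts = pg$dup_counts, diff_tests = st$diff_tests)
  })

  report <- structure(list(
    sim = sim, calls = calls, call_summaries = call_summaries,
    features = features, metagene = metagene,
    expression_categories = expression_categories,
    classes = pg$classes, class_counts = pg$class_counts,
    dup_counts = pg$dup_counts, dup_ratio = pg$dup_ratio,
    diff_tests = st$diff_tests, correlation = st$correlation,
    DE = st$DE, truth_recovery = truth_recovery,
    thresholds = thresholds
  ), class = "pangenome_report")

  if (!is.null(out_dir)) {
    stage("write_report", write_report(report, out_dir))
  }
  report
}

#' Write a pipeline report to a directory
#'
#' @param report A `pangenome_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) fwrite(x, file.path(out_dir, f), sep = "\t", na = "NA")
  w(report$calls[, .(gene_id, genome, mCG, mCHG, n_sites_CG, n_sites_CHG,
                     label)], "epiallele_calls.tsv")
  w(report$call_summaries, "epiallele_counts.tsv")
  w(report$classes[, .(pangene_id, core, excluded, class, subtype,
                       singleton_epiallele)], "pangene_classes.tsv")
  w(report$dup_counts, "duplicate_epiallele_counts.tsv")
  w(report$diff_tests, "difference_tests.tsv")
  w(report$correlation$mCG$summary, "correlation_mCG.tsv")
  w(report$correlation$mCHG$summary, "correlation_mCHG.tsv")
  w(report$expression_categories[, .N, by = .(genome, category)],
    "expression_categories.tsv")
  if (!is.null(report$metagene)) w(report$metagene, "metagene_profile.tsv")
  if (!is.null(report$features)) w(report$features$by_epiallele,
                                   "features_by_epiallele.tsv")
  if (!is.null(report$sim$models)) {
    for (g in report$sim$genomes) {
      write_tem_bed(report$calls[genome == g], report$sim$models[[g]],
                    file.path(out_dir, paste0(g, "_teM.bed")))
    }
  }
  cfg <- report$sim$cfg
  keys <- names(cfg)[vapply(cfg, function(v)
    is.numeric(v) || is.character(v) || is.logical(v), TRUE)]
  cfg_lines <- unlist(lapply(keys, function(k) {
    paste0("sim.", k, " = ", paste(cfg[[k]], collapse = ","))
  }))
  thr <- report$thresholds
  thr_lines <- paste0("threshold.", names(thr), " = ",
                      vapply(thr, paste, "", collapse = ","))
  writeLines(c(cfg_lines, thr_lines), file.path(out_dir, "run_config.txt"))

  s <- c(
    "pan-genome epiallele analysis summary",
    sprintf("genomes: %d  pangenes: %d", length(report$sim$genomes),
            length(report$sim$pangene_table$pangene_ids)),
    sprintf("epiallele calls (all genomes): %s",
            paste(sprintf("%s=%d", report$call_summaries$label,
                          report$call_summaries$n)[
                            seq_len(min(5, nrow(report$call_summaries)))],
                  collapse = " ")),
    sprintf("pangene classes: %s",
            paste(sprintf("%s=%d", report$class_counts$class,
                          report$class_counts$N), collapse = " ")),
    if (!is.null(report$dup_ratio))
      sprintf("1-to-N vs stable duplication fold (UM/gbM): %.2f",
              report$dup_ratio$fold_um_vs_gbm),
    sprintf("median gbM-UM TPM difference (%% of UM mean), by tissue:"),
    sprintf("  %s: %.2f%% (sign test p = %.3g)",
            report$diff_tests$tissue, report$diff_tests$normalized_median_pct,
            report$diff_tests$sign_test_p)
  )
  writeLines(s[!vapply(s, is.null, TRUE)], file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
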