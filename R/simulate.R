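TE_SUPERFAMILIES <- c("hAT", "Gypsy", "Copia", "CACTA", "Mutator", "LINE",
                      "Helitron", "PIF-Harbinger", "Tc1-Mariner")

#' Configuration for the synthetic pan-genome generator
#'
#' Defines the statistical structure of a simulated pan-genome: per-gene
#' epiallele frequencies, beta-binomial site-level methylation around
#' type-specific means, tandem-duplication frequency and copy-number
#' distribution, epiallele switch rates for duplicated copies, and a
#' multiplicative expression model with a tunable gene-body-methylation
#' expression effect.
#'
#' Epiallele frequencies are normalized to sum to one. Methylation means
#' reflect the bimodal genic pattern seen in maize leaf methylomes:
#' unmethylated genes near zero in both CG and CHG contexts, gbM genes
#' highly CG-methylated with near-zero CHG, and teM genes highly methylated
#' in both. Sequencing depth averages 20x. Duplicate switch-rate defaults
#' follow the observed pooled duplicate epiallele proportions (e.g. 1.5% of
#' duplicates of UM singletons are teM). The expression effect `delta_gbm`
#' multiplies gbM-gene expression by `1 + delta_gbm` (default 0.03, i.e.
#' about 3% higher steady-state expression than UM), attenuated to
#' `delta_endosperm` in endosperm; teM genes are silenced by `tem_mult`.
#'
#' @param n_genomes Number of genomes (default 26).
#' @param n_pangenes Number of pangenes (default 2000).
#' @param tissues Tissue names (default: 10 maize tissues).
#' @param epiallele_freq Named base frequencies for UM/gbM/teM singleton
#'   epialleles (normalized internally).
#' @param meth_means List per type of named CG/CHG mean methylation levels.
#' @param chh_mean Genic CHH mean level.
#' @param chh_upstream_mean CHH mean in the 500 bp upstream of the TSS for
#'   UM/gbM genes (mCHH island).
#' @param beta_concentration Concentration of the per-site beta
#'   distribution around the type mean.
#' @param cg_sites_mean,chg_sites_mean,chh_sites_mean Mean covered
#'   cytosines per gene and context (Poisson, with a floor of 45 for CG and
#'   CHG so most genes pass the 40/40 coverage rule).
#' @param low_coverage_frac Fraction of genes given only 15-35 CG/CHG sites
#'   to exercise the low-coverage path.
#' @param depth_mean Mean read depth per site (Poisson).
#' @param p_tandem Probability that a pangene carries tandem duplicates in
#'   at least one genome.
#' @param dup_cells_mean Mean number of duplicated genomes per tandem
#'   pangene (1 plus Poisson).
#' @param copy_number_mu Negative-binomial mean of copies beyond 2 per
#'   duplicate cell (copy number capped at 47).
#' @param frac_partial_dup Fraction of duplicate genes that are partial
#'   (CDS length far from the singleton median, removed by the intact
#'   filter).
#' @param switch_rates Named list per singleton type of switch
#'   probabilities to the other types for duplicated copies.
#' @param singleton_unstable_frac Fraction of singleton-only pangenes
#'   carrying a second singleton epiallele type (unstable pangenes).
#' @param p_noncore Fraction of pangenes missing from 1-3 genomes.
#' @param p_coord Fraction of pangenes with one coordinates-only cell
#'   (homologous DNA, no annotation).
#' @param baseline_meanlog,baseline_sdlog Log-normal per-pangene expression
#'   baseline.
#' @param tissue_sdlog Spread of fixed per-tissue expression multipliers.
#' @param noise_sdlog Per-gene, per-tissue log-normal expression noise
#'   (mean 1).
#' @param delta_gbm gbM expression effect (gbM genes expressed
#'   `1 + delta_gbm` times the UM level).
#' @param delta_endosperm gbM effect in endosperm.
#' @param tem_mult teM expression multiplier.
#' @param cds_meanlog,cds_sdlog,cds_min Log-normal pangene CDS length (bp).
#' @param exon_mean Mean exons per gene (1 plus Poisson).
#' @param n_chrom Chromosomes per genome.
#' @param flank_bp Flank width receiving simulated sites (for metagene
#'   profiles).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 26L, n_pangenes = 2000L,
                       tissues = DEFAULT_TISSUES,
                       epiallele_freq = c(UM = 0.55, gbM = 0.31, teM = 0.12),
                       meth_means = list(UM = c(CG = 0.01, CHG = 0.01),
                                         gbM = c(CG = 0.80, CHG = 0.02),
                                         teM = c(CG = 0.85, CHG = 0.85)),
                       chh_mean = 0.02, chh_upstream_mean = 0.08,
                       beta_concentration = 15,
                       cg_sites_mean = 60, chg_sites_mean = 60,
                       chh_sites_mean = 60, low_coverage_frac = 0.03,
                       depth_mean = 20,
                       p_tandem = 0.24, dup_cells_mean = 0.5,
                       copy_number_mu = 1.2, frac_partial_dup = 0.12,
                       switch_rates = list(UM = c(gbM = 0.007, teM = 0.015),
                                           gbM = c(UM = 0.069, teM = 0.036),
                                           teM = c(UM = 0.05, gbM = 0.02)),
                       singleton_unstable_frac = 0.035,
                       p_noncore = 0.10, p_coord = 0.05,
                       baseline_meanlog = log(15), baseline_sdlog = 0.35,
                       tissue_sdlog = 0.25, noise_sdlog = 0.2,
                       delta_gbm = 0.03, delta_endosperm = 0.005,
                       tem_mult = 0.02,
                       cds_meanlog = log(1200), cds_sdlog = 0.4,
                       cds_min = 500L,
                       exon_mean = 2, n_chrom = 10L, flank_bp = 3000L) {
  if (any(epiallele_freq < 0) || sum(epiallele_freq) <= 0 ||
      !all(DEFINED_EPIALLELES %in% names(epiallele_freq))) {
    stop("invalid epiallele frequency vector")
  }
  epiallele_freq <- epiallele_freq[DEFINED_EPIALLELES] / sum(epiallele_freq)
  for (t in names(switch_rates)) {
    if (any(switch_rates[[t]] < 0) || sum(switch_rates[[t]]) > 1) {
      stop("invalid switch rates for ", t)
    }
  }
  stopifnot(p_tandem + singleton_unstable_frac <= 1, n_genomes >= 4)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# pangene/cell/gene scaffold with true epiallele types and CDS lengths
sim_scaffold <- function(cfg) {
  n <- cfg$n_pangenes
  G <- cfg$n_genomes
  genomes <- sprintf("G%02d", seq_len(G))
  pid <- sprintf("PG%05d", seq_len(n))
  base_type <- sample(DEFINED_EPIALLELES, n, replace = TRUE,
                      prob = cfg$epiallele_freq)
  archetype <- sample(c("tandem", "unstable", "plain"), n, replace = TRUE,
                      prob = c(cfg$p_tandem, cfg$singleton_unstable_frac,
                               1 - cfg$p_tandem - cfg$singleton_unstable_frac))
  noncore <- stats::runif(n) < cfg$p_noncore
  has_coord <- stats::runif(n) < cfg$p_coord
  L_pan <- pmax(cfg$cds_min,
                round(stats::rlnorm(n, cfg$cds_meanlog, cfg$cds_sdlog)))

  # one random within-pangene genome order drives all without-replacement
  # draws (missing cells, coordinate cells, duplicate cells, second-type
  # genomes), keeping the scaffold fully vectorized
  cells <- data.table(pg = rep(seq_len(n), each = G),
                      genome = rep(genomes, n),
                      u = stats::runif(n * G))
  setorder(cells, pg, u)
  cells[, rk := seq_len(.N), by = pg]

  n_missing <- fifelse(noncore, sample(1:3, n, replace = TRUE), 0L)
  cells[, status := "singleton"]
  cells[rk <= n_missing[pg], status := "missing"]
  coord_ok <- has_coord & (G - n_missing) > 4L
  cells[coord_ok[pg] & rk == n_missing[pg] + 1L, status := "coord"]
  n_special <- n_missing + as.integer(coord_ok)
  avail <- G - n_special

  k_dup <- pmin(1L + stats::rpois(n, cfg$dup_cells_mean), pmax(0L, avail - 2L))
  k_dup[archetype != "tandem" | avail < 3L] <- 0L
  cells[archetype[pg] == "tandem" & rk > n_special[pg] &
          rk <= n_special[pg] + k_dup[pg], status := "dup"]

  # unstable pangenes: the second singleton type is drawn among the other
  # types in proportion to their base frequencies
  second <- vapply(seq_len(n), function(i) {
    if (archetype[i] != "unstable") return(NA_character_)
    others <- setdiff(DEFINED_EPIALLELES, base_type[i])
    pr <- cfg$epiallele_freq[others]
    if (sum(pr) <= 0) pr <- rep(1, length(others))
    sample(others, 1L, prob = pr)
  }, "")
  k2 <- pmax(2L, pmin(avail - 2L, stats::rbinom(n, G, 0.4)))
  k2[archetype != "unstable" | avail < 4L] <- 0L
  cells[, singleton_type := base_type[pg]]
  cells[k2[pg] > 0L & rk > n_special[pg] & rk <= n_special[pg] + k2[pg],
        singleton_type := second[pg]]

  # explode duplicate cells into copies
  cells[, copies := 1L]
  cells[status == "dup",
        copies := pmin(47L, 2L + stats::rnbinom(.N, size = 0.8,
                                                mu = cfg$copy_number_mu))]
  present <- cells[!status %in% c("missing", "coord")]
  genes <- present[rep(seq_len(.N), copies)]
  genes[, copy := seq_len(.N), by = .(pg, genome)]
  genes[, is_dup := status == "dup"]
  genes[, true_type := singleton_type]
  # duplicated copies inherit the singleton type, then switch
  for (bt in DEFINED_EPIALLELES) {
    di <- which(genes$is_dup & genes$singleton_type == bt)
    if (!length(di)) next
    sw <- cfg$switch_rates[[bt]]
    genes[di, true_type := sample(c(bt, names(sw)), length(di),
                                  replace = TRUE,
                                  prob = c(1 - sum(sw), sw))]
  }
  genes[, partial := is_dup & stats::runif(.N) < cfg$frac_partial_dup]
  genes[, cds_len := as.integer(round(L_pan[pg] * stats::runif(.N, 0.97, 1.03)))]
  genes[partial == TRUE,
        cds_len := as.integer(round(L_pan[pg] * stats::runif(.N, 0.3, 0.7)))]
  genes[, `:=`(pangene_id = pid[pg], base_type = base_type[pg])]
  genes[, gene_id := paste0(genome, "_", pangene_id, "_", copy)]
  setorder(genes, pangene_id, genome, copy)
  genes <- genes[, .(pangene_id, genome, gene_id, copy, is_dup, partial,
                     cds_len, base_type, true_type)]

  special_cells <- cells[status %in% c("missing", "coord"),
                         .(pangene_id = pid[pg], genome, cell_type = status)]
  truth_pangenes <- data.table(pangene_id = pid, base_type = base_type,
                               archetype = archetype, noncore = noncore,
                               second_type = second, median_cds_len = L_pan)
  list(genes = genes, special_cells = special_cells,
       truth_pangenes = truth_pangenes, genomes = genomes, pangene_ids = pid)
}

# exon/intron/UTR structure and genomic layout for one genome
sim_models_genome <- function(gg, cfg) {
  # gg: truth gene rows of one genome, ordered pangene then copy
  ng <- nrow(gg)
  utr_lack_p <- c(UM = 0.063, gbM = 0.004, teM = 0.59)
  lacks_utr <- stats::runif(ng) < utr_lack_p[gg$true_type]
  u5 <- fifelse(lacks_utr, 0L, 150L)
  u3 <- fifelse(lacks_utr, 0L, 150L)
  # cap exon count so every exon keeps >= 30 bp of CDS
  n_ex <- pmin(1L + stats::rpois(ng, cfg$exon_mean),
               pmax(1L, gg$cds_len %/% 60L))
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  # split CDS length into exon pieces (each at least 30 bp)
  pieces <- data.table(g = rep(seq_len(ng), n_ex))
  pieces[, w := stats::rgamma(.N, 2, 1)]
  pieces[, frac := w / sum(w), by = g]
  pieces[, len := pmax(30L, as.integer(round(frac * gg$cds_len[g])))]
  pieces[, len := {
    d <- gg$cds_len[g[1L]] - sum(len)
    i <- which.max(len)
    len[i] <- len[i] + d
    len
  }, by = g]
  pieces[, intron := c(as.integer(100L + round(stats::rexp(.N - 1L, 1 / 400))), 0L),
         by = g]

  # per-gene span and chromosome layout
  span_core <- pieces[, .(cds_total = sum(len), intron_total = sum(intron)),
                      by = g]
  span <- span_core$cds_total + span_core$intron_total + u5 + u3
  chrom_i <- ((match(gg$pangene_id, unique(gg$pangene_id)) - 1L) %%
                cfg$n_chrom) + 1L
  ord <- order(chrom_i, gg$pangene_id, gg$copy)
  gap <- 7000L
  start <- integer(ng)
  off <- rep(5000L, cfg$n_chrom)
  for (k in ord) {
    start[k] <- off[chrom_i[k]]
    off[chrom_i[k]] <- off[chrom_i[k]] + span[k] + gap
  }
  chrom <- paste0("chr", chrom_i)

  # assemble interval tables; low-coordinate pad is the 5' UTR on + strand
  pad_lo <- fifelse(strand == "+", u5, u3)
  pieces[, gstart := start[g] + pad_lo[g]]
  pieces[, cum_intron := cumsum(c(0L, head(intron, -1L))), by = g]
  pieces[, cum_cds := cumsum(c(0L, head(len, -1L))), by = g]
  pieces[, piece_start := gstart + cum_cds + cum_intron]
  pieces[, piece_end := piece_start + len]

  cds <- pieces[, .(gene_id = gg$gene_id[g], chrom = chrom[g],
                    start = piece_start, end = piece_end)]
  exons <- copy(cds)
  # extend terminal exons over the UTRs
  first_idx <- pieces[, .I[1L], by = g]$V1
  last_idx <- pieces[, .I[.N], by = g]$V1
  exons[first_idx, start := start - pad_lo[pieces$g[first_idx]]]
  pad_hi <- fifelse(strand == "+", u3, u5)
  exons[last_idx, end := end + pad_hi[pieces$g[last_idx]]]

  mk_utr <- function(len_vec, at_low) {
    sel <- which(len_vec > 0L)
    if (!length(sel)) return(NULL)
    data.table(gene_id = gg$gene_id[sel], chrom = chrom[sel],
               start = fifelse(at_low[sel], start[sel],
                               start[sel] + span[sel] - len_vec[sel]),
               end = fifelse(at_low[sel], start[sel] + len_vec[sel],
                             start[sel] + span[sel]))
  }
  utr5 <- mk_utr(u5, strand == "+")
  utr3 <- mk_utr(u3, strand == "-")

  genes <- data.table(gene_id = gg$gene_id, chrom = chrom, strand = strand,
                      start = start, end = start + span)
  gene_models(genes, cds = cds, exons = exons, utr5 = utr5, utr3 = utr3)
}

# beta-binomial site records for one genome's genes (CDS + flanks)
sim_sites_genome <- function(gg, models, cfg) {
  ng <- nrow(gg)
  lowcov <- stats::runif(ng) < cfg$low_coverage_frac
  n_cg <- fifelse(lowcov, sample(15:35, ng, replace = TRUE),
                  pmax(45L, stats::rpois(ng, cfg$cg_sites_mean)))
  n_chg <- fifelse(lowcov, sample(15:35, ng, replace = TRUE),
                   pmax(45L, stats::rpois(ng, cfg$chg_sites_mean)))
  n_chh <- stats::rpois(ng, cfg$chh_sites_mean)
  total <- n_cg + n_chg + n_chh
  L <- gg$cds_len
  # CDS space may be shorter than the requested site count for tiny genes
  total <- pmin(total, L)

  sites <- data.table(g = rep(seq_len(ng), total))
  sites[, k := seq_len(.N), by = g]
  sites[, offset := as.integer(floor((k - stats::runif(.N)) * L[g] / total[g]))]
  # contexts in per-gene proportions, shuffled within each gene
  c1 <- pmin(n_cg, total)
  c2 <- pmin(n_chg, pmax(0L, total - c1))
  c3 <- total - c1 - c2
  labs <- rep.int(rep.int(c("CG", "CHG", "CHH"), ng),
                  as.vector(rbind(c1, c2, c3)))
  ord <- order(sites$g, stats::runif(nrow(sites)))
  context <- character(nrow(sites))
  context[ord] <- labs
  sites[, context := context]

  # map CDS-space offsets to genome coordinates via cumulative CDS pieces
  cds <- copy(models$cds)
  cds[, g := match(gene_id, gg$gene_id)]
  setorder(cds, g, start)
  cds[, len := end - start]
  cds[, cum_start := cumsum(c(0L, head(len, -1L))), by = g]
  cds[, cum_end := cum_start + len]
  setkey(cds, g, cum_start, cum_end)
  sites[, `:=`(o1 = offset, o2 = offset + 1L)]
  m <- foverlaps(sites, cds, by.x = c("g", "o1", "o2"),
                 by.y = c("g", "cum_start", "cum_end"), type = "within",
                 nomatch = NULL)
  m <- m[o1 >= cum_start & o1 < cum_end]
  m[, pos0 := start + (o1 - cum_start)]
  genic <- m[, .(g, chrom, pos0, context)]

  # flank sites: 10 CG + 10 CHG + 20 CHH per 3 kb flank, each side
  gtab <- models$genes
  fl <- rbindlist(lapply(c("up", "down"), function(side) {
    nf <- c(CG = 10L, CHG = 10L, CHH = 20L)
    f <- data.table(g = rep(seq_len(ng), each = sum(nf)),
                    context = rep(rep(names(nf), nf), ng))
    f[, k := rep.int(seq_len(sum(nf)), ng)]
    f[, off := as.integer(floor((k - stats::runif(.N)) * cfg$flank_bp / sum(nf)))]
    low_side <- (side == "up") == (gtab$strand == "+")
    f[, pos0 := fifelse(low_side[g],
                        gtab$start[g] - cfg$flank_bp + off,
                        gtab$end[g] + off)]
    f[, chrom := gtab$chrom[g]]
    f[, side := side]
    f[, .(g, chrom, pos0, context, side)]
  }))
  genic[, side := "genic"]
  allsites <- rbind(genic, fl)

  # per-site beta level around the type/context/position mean
  typ <- gg$true_type
  mm_mat <- do.call(rbind, lapply(cfg$meth_means, function(x) x[c("CG", "CHG")]))
  colnames(mm_mat) <- c("CG", "CHG")
  tr <- typ[allsites$g]
  ctx <- allsites$context
  genic <- allsites$side == "genic"
  mu <- rep(cfg$chh_mean, nrow(allsites))
  sel <- genic & ctx != "CHH"
  mu[sel] <- mm_mat[cbind(tr[sel], ctx[sel])]
  # flanks: teM methylation extends across TSS/polyA; UM/gbM flanks are low
  sel <- !genic & ctx != "CHH"
  mu[sel] <- fifelse(tr[sel] == "teM", mm_mat["teM", "CG"], 0.02)
  mu[!genic & ctx == "CHH" & tr == "teM"] <- 0.05
  # mCHH island just upstream of the TSS for UM/gbM genes
  up_bump <- allsites$side == "up" & ctx == "CHH" & tr != "teM" &
    fifelse(gtab$strand[allsites$g] == "+",
            gtab$start[allsites$g] - allsites$pos0 <= 500L,
            allsites$pos0 - gtab$end[allsites$g] < 500L)
  mu[up_bump] <- cfg$chh_upstream_mean
  data.table::set(allsites, j = "mu", value = mu)

  conc <- cfg$beta_concentration
  allsites[, p := stats::rbeta(.N, mu * conc, (1 - mu) * conc)]
  allsites[, n_total := stats::rpois(.N, cfg$depth_mean)]
  allsites <- allsites[n_total >= 1L]
  allsites[, n_meth := stats::rbinom(.N, n_total, p)]
  out <- allsites[, .(chrom, strand_base = "C", pos = pos0 + 1L,
                      context,
                      subcontext = c(CG = "CG", CHG = "CA", CHH = "CC")[context],
                      level = n_meth / n_total, n_meth, n_total)]
  setorder(out, chrom, pos)
  out[]
}

# gene-level methylation summaries (fast mode, no site records)
sim_gene_meth <- function(gg, cfg) {
  ng <- nrow(gg)
  lowcov <- stats::runif(ng) < cfg$low_coverage_frac
  n_cg <- fifelse(lowcov, sample(15:35, ng, replace = TRUE),
                  pmax(45L, stats::rpois(ng, cfg$cg_sites_mean)))
  n_chg <- fifelse(lowcov, sample(15:35, ng, replace = TRUE),
                   pmax(45L, stats::rpois(ng, cfg$chg_sites_mean)))
  n_chh <- stats::rpois(ng, cfg$chh_sites_mean)
  conc <- cfg$beta_concentration
  lvl <- function(mu, nsites) {
    # averaging over nsites beta-distributed sites shrinks the variance;
    # approximate the gene-level mean with a beta at scaled concentration,
    # then add binomial read-sampling noise
    cg <- conc * pmax(1L, nsites) / 3
    m <- stats::rbeta(ng, mu * cg, (1 - mu) * cg)
    reads <- pmax(1L, as.integer(nsites * cfg$depth_mean))
    stats::rbinom(ng, reads, m) / reads
  }
  mm <- cfg$meth_means
  mu_cg <- vapply(mm, `[[`, 0, "CG")[gg$true_type]
  mu_chg <- vapply(mm, `[[`, 0, "CHG")[gg$true_type]
  data.table(gene_id = gg$gene_id,
             mCG = lvl(mu_cg, n_cg), mCHG = lvl(mu_chg, n_chg),
             mCHH = lvl(rep(cfg$chh_mean, ng), n_chh),
             n_sites_CG = n_cg, n_sites_CHG = n_chg, n_sites_CHH = n_chh)
}

# TE annotations for one genome
sim_te_genome <- function(gg, models, cfg) {
  gtab <- models$genes
  ng <- nrow(gg)
  introns <- models$exons[, derive_introns(.SD), by = gene_id,
                          .SDcols = c("start", "end")]
  p_in <- c(UM = 0.12, gbM = 0.45, teM = 0.20)[gg$true_type]
  want_in <- gg$gene_id[stats::runif(ng) < p_in]
  ti <- introns[gene_id %in% want_in]
  ti <- ti[ti[, .I[sample(.N, 1L)], by = gene_id]$V1]
  ti <- ti[end - start >= 120L]
  if (nrow(ti)) {
    ti[, te_len := pmin(end - start, sample(150:800, .N, replace = TRUE))]
    ti[, te_start := start + sapply(pmax(1L, end - start - te_len), sample, size = 1L) - 1L]
    ti[, te_end := pmin(end, te_start + te_len)]
  }
  p_cds <- c(UM = 0.03, gbM = 0.05, teM = 0.35)[gg$true_type]
  want_cds <- gg$gene_id[stats::runif(ng) < p_cds]
  tc <- models$cds[gene_id %in% want_cds]
  tc <- tc[tc[, .I[which.max(end - start)], by = gene_id]$V1]
  tc <- tc[end - start >= 120L]
  if (nrow(tc)) {
    tc[, olap := pmin(end - start, sample(110:300, .N, replace = TRUE))]
    tc[, `:=`(te_start = end - olap, te_end = end + 200L)]
  }
  # background insertions in intergenic spacers
  bg_sel <- stats::runif(ng) < 0.2
  bg <- data.table(chrom = gtab$chrom[bg_sel],
                   te_start = gtab$start[bg_sel] - 3900L,
                   te_end = gtab$start[bg_sel] - 3400L,
                   gene_id = NA_character_)
  chrom_of <- setNames(gtab$chrom, gtab$gene_id)
  te <- rbindlist(list(
    if (nrow(ti)) data.table(chrom = chrom_of[ti$gene_id],
                             te_start = ti$te_start, te_end = ti$te_end,
                             gene_id = ti$gene_id) else NULL,
    if (nrow(tc)) data.table(chrom = chrom_of[tc$gene_id],
                             te_start = tc$te_start, te_end = tc$te_end,
                             gene_id = tc$gene_id) else NULL,
    bg))
  if (nrow(te) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), superfamily = character()))
  }
  te[, superfamily := sample(TE_SUPERFAMILIES, .N, replace = TRUE)]
  out <- te[, .(chrom, start = as.integer(te_start), end = as.integer(te_end),
                superfamily)]
  setorder(out, chrom, start)
  out[]
}

#' Simulate a complete synthetic pan-genome dataset
#'
#' Generates internally consistent synthetic inputs with recorded ground
#' truth: per-genome gene annotations, site-level methylomes (beta-binomial
#' around type-specific means, including flanking sequence so metagene
#' profiles are meaningful), TE annotations, a pangene table with missing
#' and coordinates-only cells and tandem-duplicate cells, and per-genome
#' TPM matrices produced by a multiplicative expression model with a gbM
#' expression effect.
#'
#' Randomness comes from the R session RNG: call `set.seed()` first for
#' reproducible output.
#'
#' @param cfg A [sim_config()].
#' @param level Detail level: `"sites"` (full site-level methylomes, the
#'   default), `"gene"` (per-gene methylation summaries only, much faster),
#'   or `"expression"` (no methylation measurements; epialleles available
#'   only as truth).
#' @return A list of class `pangenome_sim` with elements `cfg`, `genomes`,
#'   `pangene_table` (a [pangene_table()]), `models` (named list of
#'   [gene_models()], `"sites"` level only), `sites` (named list of site
#'   tables, `"sites"` level only), `gene_meth` (named list of per-gene
#'   methylation summaries, `"gene"` level), `te` (named list of TE
#'   tables), `tpm` (named list of gene x tissue TPM matrices),
#'   `cds_lengths` (named vector over all genes) and `truth` (list with
#'   `genes` and `pangenes` tables).
#' @export
simulate_pangenome <- function(cfg = sim_config(),
                               level = c("sites", "gene", "expression")) {
  level <- match.arg(level)
  sc <- sim_scaffold(cfg)
  genes <- sc$genes
  genomes <- sc$genomes

  models <- NULL
  sites <- NULL
  gene_meth <- NULL
  te <- NULL
  if (level == "sites") {
    models <- list()
    sites <- list()
    te <- list()
    for (g in genomes) {
      gg <- genes[genome == g]
      setorder(gg, pangene_id, copy)
      mod <- sim_models_genome(gg, cfg)
      models[[g]] <- mod
      sites[[g]] <- sim_sites_genome(gg, mod, cfg)
      te[[g]] <- sim_te_genome(gg, mod, cfg)
    }
  } else if (level == "gene") {
    gene_meth <- list()
    for (g in genomes) {
      gg <- genes[genome == g]
      setorder(gg, pangene_id, copy)
      gene_meth[[g]] <- sim_gene_meth(gg, cfg)
    }
  }

  # expression: pangene baseline x tissue effect x epiallele multiplier
  n_tis <- length(cfg$tissues)
  B <- setNames(stats::rlnorm(cfg$n_pangenes, cfg$baseline_meanlog,
                              cfg$baseline_sdlog), sc$pangene_ids)
  tis_eff <- stats::rlnorm(n_tis, 0, cfg$tissue_sdlog)
  tis_eff <- setNames(tis_eff / mean(tis_eff), cfg$tissues)
  tpm <- list()
  for (g in genomes) {
    gg <- genes[genome == g]
    setorder(gg, pangene_id, copy)
    mult <- matrix(1, nrow(gg), n_tis, dimnames = list(gg$gene_id, cfg$tissues))
    mult[gg$true_type == "gbM", ] <- 1 + cfg$delta_gbm
    if ("endosperm" %in% cfg$tissues) {
      mult[gg$true_type == "gbM", "endosperm"] <- 1 + cfg$delta_endosperm
    }
    mult[gg$true_type == "teM", ] <- cfg$tem_mult
    noise <- matrix(stats::rlnorm(nrow(gg) * n_tis, -cfg$noise_sdlog^2 / 2,
                                  cfg$noise_sdlog), nrow(gg), n_tis)
    m <- B[gg$pangene_id] * mult *
      matrix(tis_eff, nrow(gg), n_tis, byrow = TRUE) * noise
    dimnames(m) <- list(gg$gene_id, cfg$tissues)
    tpm[[g]] <- m
  }

  # pangene table: genes joined by ";", plus missing and coord cells
  cells <- genes[, .(cell = paste(gene_id, collapse = ";")),
                 by = .(pangene_id, genome)]
  spec <- sc$special_cells
  if (nrow(spec)) {
    coord <- spec[cell_type == "coord"]
    coord[, cell := sprintf("chr%d:%d-%d",
                            (match(pangene_id, sc$pangene_ids) - 1L) %%
                              cfg$n_chrom + 1L,
                            1000L + 10L * match(pangene_id, sc$pangene_ids),
                            2000L + 10L * match(pangene_id, sc$pangene_ids))]
    cells <- rbind(cells, coord[, .(pangene_id, genome, cell)])
  }
  wide <- data.table::dcast(cells, pangene_id ~ genome, value.var = "cell")
  missing_g <- setdiff(genomes, names(wide)[-1L])
  for (g in missing_g) wide[[g]] <- NA_character_
  setcolorder(wide, c("pangene_id", genomes))
  wide <- wide[match(sc$pangene_ids, pangene_id)]
  pt <- pangene_table(wide)

  truth_genes <- genes[, .(gene_id, genome, pangene_id, copy,
                           true_type, is_dup, partial, cds_len, base_type)]
  structure(list(cfg = cfg, genomes = genomes, pangene_table = pt,
                 models = models, sites = sites, gene_meth = gene_meth,
                 te = te, tpm = tpm,
                 cds_lengths = setNames(genes$cds_len, genes$gene_id),
                 truth = list(genes = truth_genes,
                              pangenes = sc$truth_pangenes,
                              delta_gbm = cfg$delta_gbm,
                              switch_rates = cfg$switch_rates)),
            class = "pangenome_sim")
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("pangenome_sim:", x$cfg$n_pangenes, "pangenes x", length(x$genomes),
      "genomes;", nrow(x$truth$genes), "genes;",
      if (is.null(x$sites)) "no" else "with", "site-level methylomes\n")
  invisible(x)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits, per genome, a CGmap methylome, a GFF3 gene annotation and a TE
#' BED file (site-level simulations) and a TPM matrix; plus the pangene
#' table (CSV) and the ground-truth tables (TSV).
#'
#' @param sim A [simulate_pangenome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    if (!is.null(sim$sites)) {
      write_cgmap(sim$sites[[g]], file.path(dir, paste0(g, ".cgmap")))
      write_gff3(sim$models[[g]], file.path(dir, paste0(g, ".gff3")))
      fwrite(sim$te[[g]], file.path(dir, paste0(g, "_te.bed")),
             sep = "\t", col.names = FALSE, quote = FALSE)
    }
    write_expression_matrix(sim$tpm[[g]], file.path(dir, paste0(g, "_tpm.tsv")))
  }
  write_pangene_table(sim$pangene_table, file.path(dir, "pangene_table.csv"))
  fwrite(sim$truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t")
  fwrite(sim$truth$pangenes, file.path(dir, "truth_pangenes.tsv"), sep = "\t")
  invisible(dir)
}

#' Compare pipeline outputs with simulation ground truth
#'
#' @param sim A [simulate_pangenome()] result.
#' @param calls Optional combined epiallele call table over all genomes
#'   (`gene_id`, `label`).
#' @param classes Optional [classify_pangenes()] result.
#' @param dup_counts Optional [count_duplicate_epialleles()] result.
#' @param diff_tests Optional [epiallele_difference_tests()] result.
#' @return List of recovery summaries: `epiallele` (confusion matrix and
#'   agreement among genes passing coverage), `classes` (class confusion
#'   against truth-derived classes), `switch_rates` (estimated vs
#'   configured), `delta` (recovered normalized median expression
#'   difference vs configured, per tissue).
#' @export
truth_compare <- function(sim, calls = NULL, classes = NULL,
                          dup_counts = NULL, diff_tests = NULL) {
  out <- list()
  tg <- sim$truth$genes
  if (!is.null(calls)) {
    calls <- as.data.table(calls)
    if (!all(calls$gene_id %in% tg$gene_id)) stop("call table has unknown gene IDs")
    m <- merge(calls[, .(gene_id, label)], tg[, .(gene_id, true_type)],
               by = "gene_id")
    covered <- m[label != "low_coverage"]
    conf <- table(truth = covered$true_type,
                  call = as.character(covered$label))
    out$epiallele <- list(
      confusion = conf,
      agreement = mean(as.character(covered$label) == covered$true_type),
      n_covered = nrow(covered), n_low_coverage = nrow(m) - nrow(covered))
  }
  if (!is.null(classes)) {
    # truth classes: apply the classification rules to true epialleles and
    # true CDS lengths (measurement-noise-free reference)
    ifix <- intact_filter(sim$pangene_table, sim$cds_lengths)
    tr_cls <- classify_pangenes(sim$pangene_table, ifix,
                                setNames(tg$true_type, tg$gene_id))
    m <- merge(as.data.table(classes)[, .(pangene_id, class)],
               tr_cls[, .(pangene_id, true_class = class)], by = "pangene_id")
    m <- m[!is.na(class) | !is.na(true_class)]
    out$classes <- list(
      confusion = table(truth = m$true_class, call = m$class, useNA = "ifany"),
      agreement = mean(fifelse(is.na(m$class), "NA", m$class) ==
                         fifelse(is.na(m$true_class), "NA", m$true_class)))
  }
  if (!is.null(dup_counts)) {
    dc <- as.data.table(dup_counts)[stratum == "min2"]
    est <- dc[, .(frac = n / sum(n), dup_epiallele), by = singleton_epiallele]
    cfg_rates <- sim$truth$switch_rates
    est[, true_rate := mapply(function(s, d) {
      if (s == d) 1 - sum(cfg_rates[[s]]) else cfg_rates[[s]][[d]]
    }, singleton_epiallele, dup_epiallele)]
    out$switch_rates <- est[]
  }
  if (!is.null(diff_tests)) {
    dt <- as.data.table(diff_tests)
    dt[, true_delta_pct := 100 * fifelse(tissue == "endosperm",
                                         sim$cfg$delta_endosperm,
                                         sim$cfg$delta_gbm)]
    out$delta <- dt[, .(tissue, normalized_median_pct, true_delta_pct,
                        sign_test_p, wilcoxon_p)]
  }
  out
}
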