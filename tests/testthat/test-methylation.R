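test_that("region methylation is the read-weighted mean over covered sites", {
  s <- make_sites(c(101L, 151L), n_meth = c(2L, 3L), n_total = c(10L, 10L))
  r <- region_methylation(s, data.frame(chrom = "chr1", start = 100L, end = 200L))
  expect_equal(r$mCG, 5 / 20)
  expect_equal(r$n_sites_CG, 2L)
  expect_true(is.na(r$mCHG))
  expect_equal(r$n_sites_CHG, 0L)
  # all-unmethylated is 0, not NA
  s2 <- make_sites(100L + seq_len(60L), n_meth = 0L, n_total = 5L)
  r2 <- region_methylation(s2, data.frame(chrom = "chr1", start = 0L, end = 1000L))
  expect_equal(r2$mCG, 0)
  expect_equal(r2$n_sites_CG, 60L)
  expect_error(region_methylation(s, data.frame(chrom = character(),
                                                start = integer(),
                                                end = integer())), "empty")
})

test_that("site-mean variant averages per-site levels equally", {
  s <- make_sites(c(101L, 151L), n_meth = c(2L, 30L), n_total = c(10L, 100L))
  reg <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(region_methylation(s, reg)$mCG, 32 / 110)
  expect_equal(region_methylation(s, reg, method = "site_mean")$mCG,
               mean(c(0.2, 0.3)))
})

test_that("region methylation matches brute-force accumulation on random fixtures", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    sites <- make_sites(sample(1:500, n),
                        context = sample(c("CG", "CHG", "CHH"), n, TRUE),
                        n_meth = 0L, n_total = sample(1:20, n, TRUE))
    sites$n_meth <- vapply(sites$n_total, function(t) sample(0:t, 1), 0L)
    sites$level <- sites$n_meth / sites$n_total
    k <- sample(1:4, 1)
    st <- sample(seq(0, 450, 10), k)
    regions <- data.frame(chrom = "chr1", start = st,
                          end = st + sample(20:120, k, TRUE))
    got <- region_methylation(sites, regions)
    want <- oracle_region_methylation(sites, regions)
    expect_equal(got$mCG, want$mCG)
    expect_equal(got$mCHG, want$mCHG)
    expect_equal(got$mCHH, want$mCHH)
    expect_equal(got$n_sites_CG, want$n_CG)
    expect_equal(got$n_sites_CHG, want$n_CHG)
  }
})

test_that("disjoint regions accumulate additively and overlaps are not double counted", {
  s <- make_sites(c(101L, 301L), n_meth = c(2L, 6L), n_total = c(10L, 10L))
  two <- region_methylation(s, data.frame(chrom = "chr1",
                                          start = c(100L, 300L),
                                          end = c(200L, 400L)))
  one <- region_methylation(s, data.frame(chrom = "chr1", start = 100L, end = 400L))
  expect_equal(two$mCG, 8 / 20)
  expect_equal(two$mCG, one$mCG)
  # overlapping intervals count each site once
  ov <- region_methylation(s, data.frame(chrom = "chr1",
                                         start = c(100L, 100L),
                                         end = c(400L, 350L)))
  expect_equal(ov$mCG, 8 / 20)
  expect_equal(ov$n_sites_CG, 2L)
})

test_that("vectorized genome methylation equals per-gene region methylation", {
  set.seed(5)
  cfg <- sim_config(n_genomes = 4, n_pangenes = 30)
  sim <- simulate_pangenome(cfg)
  g <- "G02"
  gm <- genome_methylation(sim$sites[[g]], sim$models[[g]])
  for (gid in sample(gm$gene_id, 6)) {
    one <- region_methylation(sim$sites[[g]],
                              sim$models[[g]]$cds[gene_id == gid])
    row <- gm[gene_id == gid]
    expect_equal(row$mCG, one$mCG)
    expect_equal(row$mCHG, one$mCHG)
    expect_equal(row$n_sites_CG, one$n_sites_CG)
    expect_equal(row$n_sites_CHH, one$n_sites_CHH)
  }
})

test_that("a single upstream site lands in the bin nearest the TSS", {
  m <- one_gene_model(start = 10000L, end = 12000L)
  # site 50 bp upstream of the TSS: 0-based 9950, 1-based 9951
  s <- make_sites(9951L, n_meth = 5L, n_total = 10L)
  prof <- metagene_profile(m, s)
  up <- prof[context == "CG" & window == "upstream"]
  expect_equal(up[bin_index == 30, mean_level], 0.5)
  expect_equal(up[bin_index == 30, n_genes], 1L)
  expect_true(all(is.na(prof[!(context == "CG" & window == "upstream" &
                                 bin_index == 30), mean_level])))
})

test_that("metagene profiles are strand-aware and translation-invariant", {
  plus <- one_gene_model(strand = "+", start = 10000L, end = 12000L)
  s_plus <- make_sites(9951L, n_meth = 5L, n_total = 10L)
  # minus-strand gene: 50 bp upstream of the TSS lies 3' in genome coords
  minus <- one_gene_model(strand = "-", start = 10000L, end = 12000L)
  s_minus <- make_sites(12050L, n_meth = 5L, n_total = 10L)  # 0-based 12049
  p1 <- metagene_profile(plus, s_plus)
  p2 <- metagene_profile(minus, s_minus)
  expect_equal(p1$mean_level, p2$mean_level)
  expect_equal(p1$n_genes, p2$n_genes)
  # translating the whole fixture leaves the profile unchanged
  shift <- 12345L
  plus_t <- one_gene_model(strand = "+", start = 10000L + shift,
                           end = 12000L + shift)
  p3 <- metagene_profile(plus_t, make_sites(9951L + shift, n_meth = 5L,
                                            n_total = 10L))
  expect_equal(p1$mean_level, p3$mean_level)
})

test_that("bin means are unweighted across genes", {
  g2 <- gene_models(
    data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
               start = c(10000L, 50000L), end = c(12000L, 52000L)),
    cds = data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     start = c(10000L, 50000L), end = c(12000L, 52000L)))
  # both sites in the first genic bin; gene a 0.2 (1/5), gene b 0.4 (4/10)
  s <- make_sites(c(10001L, 50001L), n_meth = c(1L, 4L), n_total = c(5L, 10L))
  prof <- metagene_profile(g2, s)
  b1 <- prof[context == "CG" & window == "genic5" & bin_index == 1]
  expect_equal(b1$mean_level, 0.3)
  expect_equal(b1$n_genes, 2L)
})

test_that("internal bins beyond a short gene are skipped", {
  m <- one_gene_model(start = 10000L, end = 10400L)  # 400 bp gene
  s <- make_sites(c(10001L, 10395L), n_meth = 1L, n_total = 2L)
  prof <- metagene_profile(m, s)
  g5 <- prof[context == "CG" & window == "genic5"]
  expect_true(all(is.na(g5[bin_index > 4, mean_level])))
  expect_equal(g5[bin_index == 1, n_genes], 1L)
  expect_error(metagene_profile(gene_models(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer()),
    cds = NULL), s), "no genes")
})
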