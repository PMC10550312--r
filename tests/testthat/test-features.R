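test_that("introns are the gaps between consecutive exons", {
  ex <- data.frame(start = c(0L, 200L), end = c(100L, 300L))
  expect_equal(derive_introns(ex),
               data.table::data.table(start = 100L, end = 200L))
  expect_equal(nrow(derive_introns(data.frame(start = 0L, end = 100L))), 0L)
  ex3 <- data.frame(start = c(500L, 0L, 200L), end = c(700L, 100L, 320L))
  tr <- derive_introns(ex3)  # input order must not matter
  expect_equal(tr$start, c(100L, 320L))
  expect_equal(tr$end, c(200L, 500L))
  expect_equal(sum(tr$end - tr$start), 280L)
  expect_error(derive_introns(data.frame(start = c(0L, 50L),
                                         end = c(100L, 150L))), "overlap")
})

test_that("merged intersection counts overlapping annotations once", {
  r <- intersect_and_merge(data.frame(start = 100L, end = 200L),
                           data.frame(start = c(150L, 160L),
                                      end = c(250L, 180L)))
  expect_equal(r$length, 50L)
  expect_equal(r$segments$start, 150L)
  expect_equal(r$segments$end, 200L)
  expect_equal(intersect_and_merge(data.frame(start = 0L, end = 10L),
                                   data.frame(start = 20L, end = 30L))$length, 0L)
  expect_equal(intersect_and_merge(data.frame(start = 5L, end = 50L),
                                   data.frame(start = 5L, end = 50L))$length, 45L)
})

test_that("merged intersection equals the per-bp oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:60) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    sa <- sample(0:900, na); sb <- sample(0:900, nb)
    a <- data.frame(start = sa, end = sa + sample(10:400, na, replace = TRUE))
    b <- data.frame(start = sb, end = sb + sample(10:400, nb, replace = TRUE))
    expect_equal(intersect_and_merge(a, b)$length,
                 oracle_overlap_length(a, b, lim = 2000L))
    # symmetric and order-invariant
    expect_equal(intersect_and_merge(b, a)$length,
                 intersect_and_merge(a[sample(na), , drop = FALSE],
                                     b[sample(nb), , drop = FALSE])$length)
  }
})

test_that("feature table computes cumulative lengths, flags and superfamilies", {
  # gene a: 2 exons with UTRs; gene b: single exon, no UTR
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      strand = c("+", "-"),
                      start = c(1000L, 9000L), end = c(2500L, 9800L))
  exons <- data.frame(gene_id = c("a", "a", "b"), chrom = "chr1",
                      start = c(1000L, 2000L, 9000L),
                      end = c(1400L, 2500L, 9800L))
  cds <- data.frame(gene_id = c("a", "a", "b"), chrom = "chr1",
                    start = c(1100L, 2000L, 9000L),
                    end = c(1400L, 2400L, 9800L))
  utr5 <- data.frame(gene_id = "a", chrom = "chr1", start = 1000L, end = 1100L)
  utr3 <- data.frame(gene_id = "a", chrom = "chr1", start = 2400L, end = 2500L)
  m <- gene_models(genes, cds = cds, exons = exons, utr5 = utr5, utr3 = utr3)
  te <- data.frame(chrom = "chr1",
                   start = c(1450L, 1500L, 9100L, 9650L),
                   end = c(1600L, 1560L, 9220L, 9800L),
                   superfamily = c("hAT", "hAT", "Gypsy", NA))
  syn <- data.frame(gene_id = "a", synteny = TRUE)
  expect_warning(ft <- feature_table(m, te = te, synteny = syn), "superfamily")
  a <- ft[ft$gene_id == "a", ]
  b <- ft[ft$gene_id == "b", ]
  expect_equal(a$utr_len_total, 200L)
  expect_equal(a$cds_len, 700L)
  expect_equal(a$exon_len_total, 900L)
  expect_equal(a$intron_len_total, 600L)
  expect_equal(a$exon_count, 2L)
  # two overlapping hAT insertions in the intron merge to [1450,1600)
  expect_equal(a$intron_te_len_total, 150L)
  expect_equal(a$te_superfamilies_in_introns[[1]], "hAT")
  expect_true(a$has_utr)
  expect_false(b$has_utr)
  # CDS-TE overlap: [9100,9220) + [9650,9800) = 120 + 150 = 270 > 100
  expect_equal(b$cds_te_overlap_len, 270L)
  expect_true(b$has_cds_te_ge100)
  expect_false(a$has_cds_te_ge100)
  expect_true(a$synteny_sorghum)
  expect_true(is.na(b$synteny_sorghum))
  # exon + intron lengths tile the transcribed span
  expect_equal(a$exon_len_total + a$intron_len_total, 2500L - 1000L)
})

test_that("the CDS-TE flag boundary follows the configured rule", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 0L, end = 1000L)
  cds <- data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = 1000L)
  m <- gene_models(genes, cds = cds)
  te100 <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                      superfamily = "hAT")
  expect_false(feature_table(m, te = te100)$has_cds_te_ge100)
  expect_true(feature_table(m, te = te100, cds_te_strict = FALSE)$has_cds_te_ge100)
  te120 <- data.frame(chrom = "chr1", start = 0L, end = 120L,
                      superfamily = "hAT")
  expect_true(feature_table(m, te = te120)$has_cds_te_ge100)
  # no TE annotation: all TE quantities are zero, not NA
  ft0 <- feature_table(m)
  expect_equal(ft0$intron_te_len_total, 0L)
  expect_equal(ft0$cds_te_overlap_len, 0L)
})
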