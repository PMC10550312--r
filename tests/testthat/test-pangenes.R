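wide6 <- function(cells) {
  as.data.frame(c(list(pangene_id = "PG1"),
                  setNames(as.list(cells), sprintf("G%02d", seq_along(cells)))))
}

test_that("pangene cells parse into genes, missing and coordinate types", {
  wide <- data.frame(pangene_id = c("PG1", "PG2"),
                     G01 = c("a1", "NA"),
                     G02 = c("b1;b2", "chr3:100-200"),
                     G03 = c(NA, "c1"))
  pt <- pangene_table(wide)
  expect_equal(sort(pt$long[cell_type == "gene", gene_id]),
               c("a1", "b1", "b2", "c1"))
  expect_equal(pt$long[pangene_id == "PG2" & genome == "G02", cell_type], "coord")
  expect_equal(pt$long[pangene_id == "PG1" & genome == "G03", cell_type],
               "missing")
  # round trip
  p <- tempfile(fileext = ".csv")
  write_pangene_table(pt, p)
  pt2 <- pangene_table(p)
  expect_equal(pt2$long[order(pangene_id, genome, gene_id)],
               pt$long[order(pangene_id, genome, gene_id)],
               ignore_attr = TRUE)
})

test_that("core status requires presence everywhere, coordinate cells included", {
  wide <- data.frame(pangene_id = c("all_genes", "one_na", "with_coord"),
                     G01 = c("a1", "b1", "c1"),
                     G02 = c("a2", "NA", "chr1:5-50"),
                     G03 = c("a3", "b3", "c3"))
  core <- core_filter(pangene_table(wide))
  expect_equal(core$core, c(TRUE, FALSE, TRUE))
})

test_that("intact filter keeps genes within 10% of the singleton median", {
  wide <- data.frame(pangene_id = "PG1", G01 = "s1", G02 = "s2", G03 = "s3",
                     G04 = "d1;d2;d3")
  pt <- pangene_table(wide)
  lens <- c(s1 = 1000, s2 = 1000, s3 = 1020, d1 = 1099, d2 = 1100, d3 = 899)
  r <- intact_filter(pt, lens)
  expect_equal(r$median_len$median_len, 1000)
  keep <- setNames(r$genes$keep, r$genes$gene_id)
  expect_true(keep[["d1"]])    # |1099-1000|/1000 < 0.10
  expect_false(keep[["d2"]])   # exactly 10% is excluded
  expect_false(keep[["d3"]])   # |899-1000| = 101
  expect_true(all(keep[c("s1", "s2", "s3")]))
  # idempotence: filtering the kept genes again changes nothing
  r2 <- intact_filter(pt, lens)
  expect_equal(r$genes, r2$genes)
  # identical lengths are all kept
  same <- intact_filter(pt, setNames(rep(500, 6), names(lens)))
  expect_true(all(same$genes$keep))
  # a pangene whose cells are all duplicates has no singleton median
  wd <- data.frame(pangene_id = "PGx", G01 = "x1;x2", G02 = "y1;y2")
  rx <- intact_filter(pangene_table(wd),
                      c(x1 = 1, x2 = 1, y1 = 1, y2 = 1))
  expect_equal(rx$excluded, "PGx")
  expect_error(intact_filter(pt, lens[-1]), "missing CDS length")
})

test_that("pangene classes follow the stability rules on worked cases", {
  # 24 UM singletons + 2 duplicated genomes -> 1-to-N with UM singletons
  cells <- c(as.list(rep("UM", 24)),
             list(c("UM", "UM", "teM"), c("UM", "gbM", "UM")))
  t1 <- toy_pangene(cells)
  c1 <- classify_pangenes(t1$pt, t1$intact, t1$epi)
  expect_equal(c1$class, "one_to_N")
  expect_equal(c1$singleton_epiallele, "UM")

  # 13 UM + 13 gbM singletons -> unstable UM-gbM
  t2 <- toy_pangene(as.list(rep(c("UM", "gbM"), 13)))
  c2 <- classify_pangenes(t2$pt, t2$intact, t2$epi)
  expect_equal(c2$class, "unstable_1to1")
  expect_equal(c2$subtype, "UM-gbM")

  # 25 gbM + 1 teM -> other (teM type below 2 genes)
  t3 <- toy_pangene(as.list(c(rep("gbM", 25), "teM")))
  expect_equal(classify_pangenes(t3$pt, t3$intact, t3$epi)$class, "other")

  # all one type -> stable
  t4 <- toy_pangene(as.list(rep("gbM", 26)))
  c4 <- classify_pangenes(t4$pt, t4$intact, t4$epi)
  expect_equal(c4$class, "stable_1to1")
  expect_equal(c4$singleton_epiallele, "gbM")

  # a single defined epiallele is not enough evidence for stability
  t5 <- toy_pangene(as.list(c("gbM", rep(NA, 25))))
  expect_equal(classify_pangenes(t5$pt, t5$intact, t5$epi)$class, "other")

  # duplicates with two singleton types -> other
  t6 <- toy_pangene(c(as.list(rep(c("UM", "gbM"), 12)),
                      list(c("UM", "UM"), "UM")))
  expect_equal(classify_pangenes(t6$pt, t6$intact, t6$epi)$class, "other")
})

test_that("classification matches the exhaustive rule oracle on 6-genome tables", {
  # all 3^6 singleton assignments over {UM, gbM, teM}
  combos <- expand.grid(rep(list(c("UM", "gbM", "teM")), 6),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cells <- as.list(unlist(combos[i, ]))
    t <- toy_pangene(cells)
    got <- classify_pangenes(t$pt, t$intact, t$epi)$class
    expect_equal(got, oracle_classify(cells), info = paste(unlist(cells),
                                                           collapse = ","))
  }
})

test_that("classification matches the oracle on randomized tables with duplicates", {
  set.seed(1234)
  for (rep in 1:300) {
    ng <- sample(4:8, 1)
    cells <- lapply(seq_len(ng), function(j) {
      k <- sample(c(1, 1, 1, 1, 2, 3), 1)
      v <- sample(c("UM", "gbM", "teM", NA), k, replace = TRUE)
      if (runif(1) < 0.05) NULL else v
    })
    # pangenes without any singleton cell have no median and are excluded
    # from classification, so keep at least one singleton in the fixture
    if (!any(vapply(cells, function(v) length(v) == 1L, TRUE))) next
    t <- toy_pangene(cells)
    got <- classify_pangenes(t$pt, t$intact, t$epi)$class
    expect_equal(got, oracle_classify(cells))
  }
})

test_that("class counts partition core pangenes after preconditions", {
  set.seed(77)
  cfg <- sim_config(n_genomes = 8, n_pangenes = 250)
  sim <- simulate_pangenome(cfg, level = "gene")
  calls <- call_epiallele(data.table::rbindlist(sim$gene_meth))
  epi <- setNames(as.character(calls$label), calls$gene_id)
  pt <- sim$pangene_table
  core <- core_filter(pt)
  intact <- intact_filter(pt, sim$cds_lengths)
  cls <- classify_pangenes(pt, intact, epi, core = core)
  n_classified <- sum(!is.na(cls$class))
  expect_equal(n_classified, sum(core$core & !cls$excluded))
  expect_equal(sum(cls$class %in% PANGENE_CLASSES, na.rm = TRUE), n_classified)
})

test_that("duplicate epiallele counting pools intact duplicates by stratum", {
  # UM singletons; one 3-copy cell (UM,UM,teM); one 4-copy cell (UM x4)
  cells <- c(as.list(rep("UM", 10)),
             list(c("UM", "UM", "teM"), c("UM", "UM", "UM", "UM")))
  t <- toy_pangene(cells)
  cls <- classify_pangenes(t$pt, t$intact, t$epi)
  expect_equal(cls$class, "one_to_N")
  cnt <- count_duplicate_epialleles(cls, t$intact, t$epi)
  min2 <- cnt[cnt$stratum == "min2" & cnt$singleton_epiallele == "UM", ]
  expect_equal(min2$n[min2$dup_epiallele == "UM"], 6L)
  expect_equal(min2$n[min2$dup_epiallele == "teM"], 1L)
  min4 <- cnt[cnt$stratum == "min4" & cnt$singleton_epiallele == "UM", ]
  expect_equal(min4$n[min4$dup_epiallele == "UM"], 4L)  # 3-copy cell excluded
  expect_equal(min4$n[min4$dup_epiallele == "teM"], 0L)
})

test_that("relative duplication ratios reproduce the worked fold change", {
  r <- relative_duplication_ratio(list(UM = 4149, gbM = 1589, teM = 232),
                                  list(UM = 7001, gbM = 5992, teM = 277))
  expect_equal(round(r$fold_um_vs_gbm, 1), 2.2)
  expect_equal(r$ratio[["UM"]], 4149 / 7001)
  eq <- relative_duplication_ratio(list(UM = 10, gbM = 10),
                                   list(UM = 10, gbM = 10))
  expect_equal(eq$fold_um_vs_gbm, 1.0)
  expect_warning(z <- relative_duplication_ratio(list(UM = 5, gbM = 3),
                                                 list(UM = 5, gbM = 0)),
                 "undefined")
  expect_true(is.na(z$ratio[["gbM"]]))
})
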