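makeFcFixture <- function() {
  # 3 Or genes: gOrA halves in the mutant on both platforms, gOrB collapses
  # in single-nucleus data, gOrC is zero in the mutant bulk samples
  cts <- cbind(matrix(c(4, 4, 4), 3, 4), matrix(c(2, 0, 4), 3, 4))
  # background gene balances the totals so CP10k ratios equal count ratios
  cts <- rbind(cts, rep(c(5, 11), each = 4))
  geno <- rep(c("WT", "mutant"), each = 4)
  ae <- toyExperiment(cts, classes = c(rep("tuning_Or", 3), "other"),
                      genotype = geno)
  design <- data.frame(sample_id = paste0("s", 1:4),
                       stage = c("D15", "D20", "D15", "D20"),
                       genotype = rep(c("WT", "mutant"), each = 2),
                       replicate = c(1, 1, 2, 2))
  # "other" balances per-sample totals so FPKM ratios equal count ratios
  bcts <- rbind(gOrA = c(100, 100, 50, 50), gOrB = c(80, 80, 60, 60),
                gOrC = c(90, 90, 0, 0), other = c(500, 500, 660, 660))
  rownames(bcts) <- c("g001", "g002", "g003", "g004")
  bt <- BulkTimecourse(bcts, design,
                       data.frame(gene_id = rownames(bcts), length = 1000))
  list(ae = ae, bt = bt)
}

test_that("fold changes follow the record rules on both platforms", {
  fx <- makeFcFixture()
  rec <- crossPlatformFC(fx$ae, fx$bt, c("g001", "g002", "g003"))
  # sn: cells have equal totals, so CP10k ratios equal count ratios
  expect_equal(rec$log2fc_sn[rec$gene_id == "g001"], -1)
  expect_true(is.na(rec$log2fc_sn[rec$gene_id == "g002"])) # zero in mutant sn
  # bulk records: totals equal per sample; gOrC zero in mutant bulk
  expect_true(is.na(rec$log2fc_bulk[rec$gene_id == "g003"]))
  expect_equal(rec$log2fc_bulk[rec$gene_id == "g001"], -1)
})

test_that("concordance has its closed-form values", {
  rec <- data.frame(log2fc_sn = c(-3, -2, -1, 0),
                    log2fc_bulk = c(-6, -4, -2, 0))
  cc <- concordance(rec)
  expect_equal(cc$pearson_r2, 1)
  expect_equal(cc$spearman_r2, 1)
  expect_equal(cc$pearson_sign, 1)
  rec$log2fc_bulk <- -rec$log2fc_sn
  cc2 <- concordance(rec)
  expect_equal(cc2$pearson_r2, 1) # sign lost in squaring
  expect_equal(cc2$pearson_sign, -1)
  rec$log2fc_bulk <- rep(0, 4)
  expect_true(is.na(concordance(rec)$pearson_r2))
  expect_error(concordance(data.frame(log2fc_sn = 1, log2fc_bulk = 1)),
               "fewer than 3")
})

test_that("spearman concordance is invariant to monotone transforms", {
  set.seed(1)
  rec <- data.frame(log2fc_sn = rnorm(50), log2fc_bulk = rnorm(50))
  base <- concordance(rec)$spearman_r2
  rec2 <- rec
  rec2$log2fc_sn <- exp(rec2$log2fc_sn)
  rec2$log2fc_bulk <- rec2$log2fc_bulk^3
  expect_equal(concordance(rec2)$spearman_r2, base, tolerance = 1e-12)
})

test_that("independent axes give near-zero concordance", {
  set.seed(2)
  hits <- vapply(1:20, function(i) {
    rec <- data.frame(log2fc_sn = rnorm(300), log2fc_bulk = rnorm(300))
    concordance(rec)$pearson_r2 < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("retained selection needs both cutoffs and is monotone", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc_sn = c(-0.2, -0.2, -3),
                    log2fc_bulk = c(-0.3, -3, -0.3))
  expect_identical(selectRetained(rec), "a")
  expect_identical(selectRetained(rec, -4, -4), c("a", "b", "c"))
  # lowering cutoffs never shrinks the set
  s1 <- selectRetained(rec, -1, -1)
  s2 <- selectRetained(rec, -2, -2)
  expect_true(all(s1 %in% s2))
})

test_that("neighbor coexpression computes jaccard and distances by hand", {
  # gene layout: Or at 1000-1500, neighbor n1 at 3000-3500, n2 far away
  anno <- data.frame(gene_id = c("or1", "n1", "n2"),
                     gene_class = c("tuning_Or", "other", "other"),
                     scaffold = "s1", start = c(1000, 3000, 50000),
                     end = c(1500, 3500, 50500), strand = "+")
  cts <- rbind(or1 = c(1, 1, 1, 0, 0, 2, 0),
               n1 = c(2, 2, 0, 1, 1, 0, 0),
               n2 = c(0, 0, 0, 0, 0, 0, 1))
  meta <- data.frame(cell_id = paste0("c", 1:7), library_id = "l",
                     genotype = "WT")
  ae <- AntennalExperiment(cts, meta, anno)
  cx <- neighborCoexpression(ae, paste0("c", 1:5), "or1")
  expect_identical(cx$neighbor_gene_id, "n1")
  expect_equal(cx$distance, 2000)
  # nonneuronal cells c1..c5: or1 in {1,2,3}, n1 in {1,2,4,5}
  expect_equal(cx$jaccard, 2 / 5)
  expect_equal(cx$nonneuronal_fraction_of_or_expression, 3 / 5)
  # identical sets -> 1; disjoint -> 0
  cts2 <- rbind(or1 = c(1, 1, 0, 0), nb = c(2, 3, 0, 0))
  ae2 <- toyExperiment(cts2, classes = c("tuning_Or", "other"))
  cx2 <- neighborCoexpression(ae2, paste0("c00", 1:4), "g001")
  expect_equal(cx2$jaccard, 1)
  cts3 <- rbind(or1 = c(1, 1, 0, 0), nb = c(0, 0, 2, 2))
  ae3 <- toyExperiment(cts3, classes = c("tuning_Or", "other"))
  cx3 <- neighborCoexpression(ae3, paste0("c00", 1:4), "g001")
  expect_equal(cx3$jaccard, 0)
})

test_that("an Or alone on its scaffold yields a missing neighbor", {
  anno <- data.frame(gene_id = c("or1", "n1"),
                     gene_class = c("tuning_Or", "other"),
                     scaffold = c("sA", "sB"), start = c(1000, 1000),
                     end = c(1500, 1500), strand = "+")
  cts <- rbind(or1 = c(1, 1), n1 = c(1, 0))
  meta <- data.frame(cell_id = c("c1", "c2"), library_id = "l",
                     genotype = "WT")
  ae <- AntennalExperiment(cts, meta, anno)
  cx <- neighborCoexpression(ae, c("c1", "c2"), "or1")
  expect_true(is.na(cx$neighbor_gene_id))
  expect_true(is.na(cx$distance))
})
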