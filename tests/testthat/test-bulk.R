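test_that("median-of-ratios matches the hand-computed example", {
  counts <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
  sf <- sizeFactorsMedianOfRatios(counts)
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-4)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2, tolerance = 1e-12)
})

test_that("size factors are equivariant and scale-invariant", {
  set.seed(1)
  counts <- matrix(rpois(60, 20) + 1, 10, 6)
  sf <- sizeFactorsMedianOfRatios(counts)
  # identical samples -> all factors 1
  expect_equal(unname(sizeFactorsMedianOfRatios(counts[, c(1, 1, 1)])),
               rep(1, 3))
  # doubling one sample doubles only its factor
  c2 <- counts
  c2[, 3] <- c2[, 3] * 2
  sf2 <- sizeFactorsMedianOfRatios(c2)
  expect_equal(sf2[3] / sf[3], 2 * (sf2[1] / sf[1]), tolerance = 1e-12)
  # the recomputed reference makes factors invariant under global scaling
  sfc <- sizeFactorsMedianOfRatios(counts * 5)
  expect_equal(unname(sfc), unname(sf), tolerance = 1e-12)
  expect_equal(sweep(counts * 5, 2, sfc, "/"),
               5 * sweep(counts, 2, sf, "/"), tolerance = 1e-12)
  expect_error(sizeFactorsMedianOfRatios(matrix(c(0, 1, 1, 0), 2, 2)),
               "no gene")
})

test_that("size factors agree with the established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  counts <- matrix(rnbinom(200, mu = 50, size = 5) + 1, 20, 10)
  ours <- sizeFactorsMedianOfRatios(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("FPKM follows its defining formula", {
  expect_equal(fpkm(matrix(100), 1000, 1e6)[1, 1], 100)
  expect_equal(fpkm(matrix(100), 2000, 1e6)[1, 1], 50)   # doubling length
  expect_equal(fpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  expect_error(fpkm(matrix(1), 0, 1e6), "positive")
  expect_error(fpkm(matrix(1), 1000, 0), "zero")
})

test_that("max-scaled trajectories behave as documented", {
  design <- data.frame(sample_id = paste0("s", 1:4),
                       stage = c("D10", "D15", "D20", "D25"),
                       genotype = "WT", replicate = 1)
  norm <- rbind(gA = c(10, 20, 40, 40), gB = c(5, 10, 20, 20))
  colnames(norm) <- design$sample_id
  st <- scaledTrajectory(norm, design, c("gA", "gB"))
  prof <- st$profiles["gA", ]
  expect_equal(sort(unname(prof)), c(0.25, 0.5, 1, 1))
  # identical shapes -> SD 0 everywhere
  expect_true(all(st$summary$sd < 1e-12))
  expect_true(all(st$profiles >= 0 & st$profiles <= 1))
  # all-zero genes are dropped with a message
  norm2 <- rbind(norm, gC = rep(0, 4))
  expect_message(st2 <- scaledTrajectory(norm2, design, rownames(norm2)),
                 "all-zero")
  expect_false("gC" %in% rownames(st2$profiles))
})

test_that("mutant Or expression collapses after D15 through the pipeline", {
  bt <- simulateBulkTimecourse(deskConfig(rng_seed = 8L))
  tr <- simTruth(bt)
  st <- scaledTrajectory(normalizeBulk(bt), as.data.frame(colData(bt)),
                         tr$or_like)
  sm <- st$summary
  d15 <- sm$mean[sm$genotype == "mutant" & sm$stage == "D15"]
  d20 <- sm$mean[sm$genotype == "mutant" & sm$stage == "D20"]
  expect_lt(d20, 0.5 * d15)
  # WT stays high
  w20 <- sm$mean[sm$genotype == "WT" & sm$stage == "D20"]
  expect_gt(w20, 0.5 * sm$mean[sm$genotype == "WT" & sm$stage == "D15"])
})

test_that("a two-gene toy recovers early/late sets from PC1 loadings", {
  design <- data.frame(sample_id = paste0("s", 1:4),
                       stage = c("D10", "D15", "D20", "D25"),
                       genotype = "WT", replicate = 1)
  counts <- rbind(A = c(400, 200, 100, 50), B = c(50, 100, 200, 400),
                  C = c(100, 100, 100, 100))
  bt <- BulkTimecourse(counts, design,
                       data.frame(gene_id = c("A", "B", "C"),
                                  length = c(1000, 1000, 1000)))
  expect_warning(ss <- stageGeneSets(bt, loadingSetSize = 1), NA)
  expect_identical(ss$early, "A")
  expect_identical(ss$late, "B")
  expect_error(stageGeneSets(bt[, 1:2], loadingSetSize = 1), "3 samples")
})

test_that("stage sets are disjoint and permutation-invariant", {
  bt <- simulateBulkTimecourse(deskConfig(rng_seed = 12L))
  ss <- stageGeneSets(bt, loadingSetSize = 200)
  expect_length(intersect(ss$early, ss$intermediate), 0)
  expect_length(intersect(ss$early, ss$late), 0)
  expect_length(intersect(ss$intermediate, ss$late), 0)
  perm <- sample(nrow(bt))
  ss2 <- stageGeneSets(bt[perm, ], loadingSetSize = 200)
  expect_setequal(ss2$early, ss$early)
  expect_setequal(ss2$intermediate, ss$intermediate)
  expect_setequal(ss2$late, ss$late)
})

test_that("Or-only PCA separates genotypes only when trajectories differ", {
  bt <- simulateBulkTimecourse(deskConfig(rng_seed = 13L))
  tr <- simTruth(bt)
  design <- as.data.frame(colData(bt))
  pc <- orPCA(bt, c(tr$or_like, tr$or_retained))
  late <- design$stage %in% c("D20", "D25")
  lab <- design$genotype[late]
  x <- pc$scores[late, 1:2, drop = FALSE]
  # silhouette of the genotype split at late stages
  d <- as.matrix(dist(x))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
  # identical matrices for both genotypes -> genotypes overlap in PC space
  cts <- assay(bt, "counts")
  matched <- sprintf("%s_%s_r%d", design$stage, "WT", design$replicate)
  ctsSame <- cts[, matched]
  colnames(ctsSame) <- design$sample_id
  btSame <- BulkTimecourse(ctsSame, design,
                           as.data.frame(rowData(bt))[, c("gene_id",
                                                          "length")])
  pcSame <- orPCA(btSame, c(tr$or_like, tr$or_retained))
  wtRows <- pcSame$scores[matched, , drop = FALSE]
  expect_lt(max(abs(pcSame$scores - wtRows)), 1e-8)
  expect_error(orPCA(bt, "early001"), "2 Or genes")
})
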