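test_that("the worked exact example gives p = 1/35", {
  res <- callGeneInCell(c(3, 4, 5), c(0, 0, 0, 1), alpha = 0.05)
  expect_equal(res$p, 1 / 35, tolerance = 1e-12)
  expect_true(res$call)
})

test_that("degenerate and wrong-direction cases behave as specified", {
  # all values tied -> p = 1, not expressing
  res <- callGeneInCell(c(0, 0, 0), c(0, 0, 0, 0))
  expect_equal(res$p, 1)
  expect_false(res$call)
  # neighborhood clearly below background -> one-sided p >= 0.5
  res2 <- callGeneInCell(c(0, 0), c(5, 6, 7))
  expect_gte(res2$p, 0.5)
  expect_false(res2$call)
  expect_error(callGeneInCell(numeric(), c(1, 2)), "empty")
})

test_that("the exact branch matches exhaustive enumeration with ties", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, m, replace = TRUE)
    expect_equal(mwuGreater(x, y), mwuOracle(x, y), tolerance = 1e-12,
                 info = paste("x:", paste(x, collapse = ","),
                              "y:", paste(y, collapse = ",")))
  }
})

test_that("the normal branch agrees with the tie-corrected reference test", {
  set.seed(2)
  for (i in 1:25) {
    x <- sample(0:5, 16, replace = TRUE) + rbinom(16, 1, 0.5) * 0.5
    y <- sample(0:5, 40, replace = TRUE)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                         correct = TRUE))$p.value
    expect_equal(mwuGreater(x, y), ref, tolerance = 1e-10)
  }
})

test_that("adding a constant to the neighborhood never increases p", {
  set.seed(3)
  for (i in 1:30) {
    x <- rpois(8, 2)
    y <- rpois(15, 2)
    p0 <- mwuGreater(x, y)
    for (d in c(0.5, 1, 3)) expect_lte(mwuGreater(x + d, y), p0 + 1e-12)
  }
})

test_that("the background draw is fixed, WT-only and nonneuronal-only", {
  res <- smallFixture()
  cls <- res$gating$cellClass
  bg1 <- drawBackground(res$snData, cls, size = 50, seed = 5)
  bg2 <- drawBackground(res$snData, cls, size = 50, seed = 5)
  expect_identical(bg1, bg2)
  g <- genotype(res$snData)[match(bg1, colnames(res$snData))]
  expect_true(all(g == "WT"))
  expect_true(all(cls[bg1] != "neuronal"))
  # exhaustive draw returns the full eligible set regardless of seed
  eligible <- colnames(res$snData)[g2 <- genotype(res$snData) == "WT" &
                                     cls != "neuronal"]
  bgAll <- drawBackground(res$snData, cls, size = length(eligible), seed = 1)
  expect_setequal(bgAll, eligible)
  expect_error(drawBackground(res$snData, cls,
                              size = length(eligible) + 1, seed = 1),
               "short by 1")
})

test_that("call matrices are order-invariant and all-false for null genes", {
  set.seed(6)
  nC <- 60
  cts <- rbind(matrix(rpois(10 * nC, 3), 10, nC),  # shared genes
               c(matrix(0, 1, nC)),                # a receptor, silent
               rep(0, nC))
  cts[11, 1:20] <- rpois(20, 4)                    # receptor in cells 1:20
  classes <- c(rep("other", 10), "tuning_Or", "orco")
  geno <- rep(c("WT", "mutant"), length.out = nC)
  ae <- toyExperiment(cts, classes = classes, genotype = geno)
  ae <- normalizeCP10kLog1p(ae)
  lat <- cbind(c(rep(0, 20), rep(5, 40)), rep(0, nC)) +
    matrix(rnorm(2 * nC, 0, 0.1), nC, 2)
  emb <- knnCluster(lat, nNeighbors = 8, resolution = 0.1, seed = 1)
  cellClass <- setNames(rep("neuronal", nC), colnames(ae))
  bg <- colnames(ae)[31:60]
  rc <- buildCallMatrix(ae, emb, bg, cellClass, alpha = 0.05)
  expect_true(all(!calls(rc)[, "g012"]))           # all-zero gene: all false
  expect_true(all(calls(rc)[1:15, "g011"]))        # expressing block called
  # permuting cells leaves calls identical after reindexing
  perm <- sample(nC)
  aeP <- ae[, perm]
  embP <- knnCluster(lat[perm, ], nNeighbors = 8, resolution = 0.1, seed = 1)
  rcP <- buildCallMatrix(aeP, embP, bg, cellClass[perm], alpha = 0.05)
  expect_equal(pvals(rcP)[colnames(ae), ], pvals(rc)[colnames(ae), ],
               tolerance = 1e-12)
  # unknown receptor ids are skipped with a warning
  expect_warning(buildCallMatrix(ae, emb, bg, cellClass,
                                 receptorGenes = c("g011", "ghost")),
                 "skipped")
})

test_that("nonneuronal cells get all-false rows with p = 1", {
  res <- smallFixture()
  rc <- res$calls
  nonneur <- names(res$gating$cellClass)[res$gating$cellClass != "neuronal"]
  expect_true(all(pvals(rc)[nonneur, ] == 1))
  expect_true(all(!calls(rc)[nonneur, ]))
})
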