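test_that("cluster gating requires all four neuron markers", {
  set.seed(1)
  nC <- 90
  markers <- c("nSyb", "fne", "Syt1", "onecut", "repo", "Mhc", "grh", "sv")
  cts <- matrix(rpois(10 * nC, 1), 10, nC)
  # cluster 0 (cells 1:30): all four neuron markers in 90% of cells
  # cluster 1 (cells 31:60): three of four
  # cluster 2 (cells 61:90): repo only
  m <- matrix(0, 8, nC)
  m[1:4, 1:30] <- rbinom(4 * 30, 1, 0.9) * 3
  m[1:3, 31:60] <- rbinom(3 * 30, 1, 0.9) * 3
  m[5, 61:90] <- rbinom(30, 1, 0.8) * 4
  cts <- rbind(cts, m)
  anno <- data.frame(gene_id = c(sprintf("x%02d", 1:10), markers),
                     gene_class = c(rep("other", 10), rep("neuron_marker", 4),
                                    "glia_marker", "muscle_marker",
                                    "epithelium_marker", "support_marker"),
                     scaffold = "s", start = 1:18, end = 2:19, strand = "+")
  meta <- data.frame(cell_id = sprintf("c%03d", 1:nC), library_id = "l",
                     genotype = "WT")
  ae <- normalizeCP10kLog1p(AntennalExperiment(cts, meta, anno))
  nbrs <- cbind((seq_len(nC) %% nC) + 1L, ((seq_len(nC) + 1L) %% nC) + 1L)
  emb <- methods::new("CellEmbedding",
                      latent = matrix(0, nC, 1),
                      neighbors = nbrs,
                      clusters = rep(0:2, each = 30),
                      varExplained = numeric(), elbow = NA_integer_)
  g <- gateClusters(ae, emb)
  expect_identical(unname(g$clusterClass[c("0", "1", "2")]),
                   c("neuronal", "other_nonneuronal", "glia"))
})

test_that("category rules reproduce the documented receptor combinations", {
  pv <- function(anyOr = FALSE, orco = FALSE, anyIr = FALSE, anyIrco = FALSE,
                 anyGr = FALSE, Rh50 = FALSE, nompC = FALSE)
    c(anyOr = anyOr, orco = orco, anyIr = anyIr, anyIrco = anyIrco,
      anyGr = anyGr, Rh50 = Rh50, nompC = nompC)
  expect_identical(assignCategory(pv(anyOr = TRUE, orco = TRUE)), "OrX_orco")
  expect_identical(assignCategory(pv(nompC = TRUE)), "mechanosensory")
  expect_identical(assignCategory(pv(orco = TRUE, anyIr = TRUE,
                                     anyIrco = TRUE)), "orco_Ir_irco")
  # a tuning Or on top of the functional Ir complex stays in that category
  expect_identical(assignCategory(pv(anyOr = TRUE, orco = TRUE,
                                     anyIr = TRUE, anyIrco = TRUE)),
                   "orco_Ir_irco")
  expect_identical(assignCategory(pv(anyOr = TRUE, orco = TRUE,
                                     anyGr = TRUE)), "OrX_orco_Gr")
  expect_identical(assignCategory(pv(anyOr = TRUE, orco = TRUE,
                                     anyIrco = TRUE)), "OrX_orco_irco")
  expect_identical(assignCategory(pv(anyGr = TRUE)), "Gr_only")
  expect_identical(assignCategory(pv(anyIr = TRUE, anyIrco = TRUE)),
                   "Ir_irco")
  expect_identical(assignCategory(pv(anyGr = TRUE, anyIrco = TRUE)),
                   "Gr_Ir_coreceptor")
  expect_identical(assignCategory(pv(orco = TRUE)), "orco_only")
  expect_identical(assignCategory(pv()), "neuron_unclassified")
})

test_that("the rule table is exhaustive over all predicate combinations", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- c("anyOr", "orco", "anyIr", "anyIrco", "anyGr",
                     "Rh50", "nompC")
  labs <- apply(combos, 1, function(r) assignCategory(as.logical(r) |>
                                                        setNames(names(combos))))
  expect_true(all(nzchar(labs)))
  expect_length(labs, 128)
})

test_that("truth-perfect calls reproduce the generator categories exactly", {
  res <- smallFixture()
  tr <- res$truth
  ae <- res$snData
  progs <- tr$cells$program[match(colnames(ae), tr$cells$cell_id)]
  receptors <- colnames(calls(res$calls))
  pv <- matrix(1, ncol(ae), length(receptors),
               dimnames = list(colnames(ae), receptors))
  for (i in seq_len(ncol(ae))) {
    genes <- tr$expressed_receptors[[progs[i]]]
    pv[i, intersect(genes, receptors)] <- 0
  }
  rcPerfect <- methods::new("ReceptorCalls", calls = pv < 0.05, pvals = pv,
                            alpha = 0.05, background = character())
  trueClass <- ifelse(tr$cells$neuronal[match(colnames(ae),
                                              tr$cells$cell_id)],
                      "neuronal",
                      tr$cells$category[match(colnames(ae),
                                              tr$cells$cell_id)])
  cats <- assignCategories(rcPerfect, trueClass,
                           as.data.frame(rowData(ae)))
  truthCat <- tr$cells$category[match(colnames(ae), tr$cells$cell_id)]
  expect_identical(unname(cats), unname(truthCat))
})

test_that("survival table matches hand arithmetic and null cases", {
  cats <- c(rep("neuronX", 80), rep("glia", 40), rep("neuronX", 10),
            rep("glia", 70))
  geno <- rep(c("WT", "mutant"), c(120, 80))
  tab <- survivalTable(cats, geno)
  nf <- attr(tab, "neuron_fraction")
  expect_equal(unname(nf["WT"]), 80 / 120, tolerance = 1e-12)
  expect_equal(unname(nf["mutant"]), 10 / 80, tolerance = 1e-12)
  expect_equal(sum(tab$fraction_WT), 1, tolerance = 1e-12)
  expect_equal(sum(tab$fraction_mutant), 1, tolerance = 1e-12)
  # identical count vectors: odds ratios 1, p = 1
  cats2 <- rep(c("a", "b"), each = 20)
  geno2 <- rep(c("WT", "mutant"), 20)
  tab2 <- survivalTable(cats2, geno2)
  expect_equal(tab2$depletion_odds_ratio, c(1, 1))
  expect_equal(tab2$p, c(1, 1))
  # Haldane-Anscombe correction keeps zero-count categories finite
  tab3 <- survivalTable(c("a", "a", "b", "b"),
                        c("WT", "WT", "mutant", "mutant"))
  expect_true(all(is.finite(tab3$depletion_odds_ratio)))
})

test_that("categories empty in both genotypes are dropped with a message", {
  cats <- factor(c("a", "a", "b"), levels = c("a", "b", "zz"))
  expect_message(tab <- survivalTable(cats, c("WT", "WT", "mutant")),
                 "dropped")
  expect_setequal(tab$category, c("a", "b"))
})
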