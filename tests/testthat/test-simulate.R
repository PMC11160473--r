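test_that("program weights must sum to one", {
  pr <- defaultPrograms()
  pr[[1]]$weight <- pr[[1]]$weight + 0.5
  expect_error(simulateAntennalSn(deskConfig(sim_n_cells_per_genotype = 50),
                                  programs = pr), "sum to 1")
})

test_that("realized mixture proportions converge to program weights", {
  cfg <- deskConfig(sim_n_cells_per_genotype = 5000, rng_seed = 3L)
  ae <- simulateAntennalSn(cfg)
  tr <- simTruth(ae)
  wt <- tr$cells[genotype(ae) == "WT", ]
  pr <- defaultPrograms()
  w <- vapply(pr, `[[`, 0, "weight")
  realized <- table(factor(wt$program, levels = names(w))) / nrow(wt)
  expect_lt(max(abs(as.numeric(realized) - w)), 0.02)
  # neuron fraction within binomial 99% CI of the set mass
  nf <- mean(wt$neuronal)
  ci <- stats::qnorm(0.995) * sqrt(0.67 * 0.33 / nrow(wt))
  expect_lt(abs(nf - 0.67), ci + 1e-9)
})

test_that("all-surviving programs give identical genotype mixtures", {
  pr <- defaultPrograms(dyingSurvival = 1)
  cfg <- deskConfig(sim_n_cells_per_genotype = 4000, rng_seed = 5L)
  ae <- simulateAntennalSn(cfg, programs = pr)
  tr <- simTruth(ae)
  g <- genotype(ae)
  # derived mutant neuron mass equals the WT mass; realized fractions agree
  expect_equal(unname(tr$neuron_mass["mutant"]),
               unname(tr$neuron_mass["WT"]))
  fWT <- mean(tr$cells$neuronal[g == "WT"])
  fMUT <- mean(tr$cells$neuronal[g == "mutant"])
  expect_lt(abs(fWT - fMUT), 0.04)
})

test_that("zero dispersion reaches the Poisson mean-variance limit", {
  cfg <- deskConfig(sim_n_cells_per_genotype = 1500, sim_dispersion = 1e-12,
                    sim_depth_sdlog = 1e-6, sim_batch_sdlog = 0,
                    rng_seed = 2L)
  ae <- simulateAntennalSn(cfg)
  tr <- simTruth(ae)
  # neuron markers share one mean across every neuronal program, so all
  # WT neurons are i.i.d. draws for these genes
  cells <- which(tr$cells$neuronal & genotype(ae) == "WT")
  cts <- as.matrix(assay(ae, "counts")[c("nSyb", "fne", "Syt1"), cells])
  ratio <- apply(cts, 1, stats::var) / rowMeans(cts)
  expect_lt(max(abs(ratio - 1)), 0.15)
  # and with substantial dispersion the variance is clearly super-Poisson
  cfg2 <- deskConfig(sim_n_cells_per_genotype = 1500, sim_dispersion = 0.5,
                     sim_depth_sdlog = 1e-6, sim_batch_sdlog = 0,
                     rng_seed = 2L)
  ae2 <- simulateAntennalSn(cfg2)
  tr2 <- simTruth(ae2)
  cells2 <- which(tr2$cells$neuronal & genotype(ae2) == "WT")
  cts2 <- as.matrix(assay(ae2, "counts")["nSyb", cells2, drop = FALSE])
  expect_gt(stats::var(cts2[1, ]) / mean(cts2[1, ]), 1.5)
})

test_that("per-cell depth follows the configured log-normal", {
  cfg <- deskConfig(sim_n_cells_per_genotype = 2500, rng_seed = 9L)
  ae <- simulateAntennalSn(cfg)
  lt <- log(colData(ae)$n_umis)
  expect_lt(abs(stats::sd(lt) - cfg$sim_depth_sdlog) / cfg$sim_depth_sdlog,
            0.15)
})

test_that("counts are nonnegative integers and truth covers every cell", {
  ae <- smallFixture()$truth
  full <- simulateAntennalSn(deskConfig(sim_n_cells_per_genotype = 200,
                                        rng_seed = 4L))
  cts <- assay(full, "counts")
  expect_true(all(cts@x >= 0))
  expect_true(all(cts@x == round(cts@x)))
  expect_setequal(simTruth(full)$cells$cell_id, colnames(full))
})

test_that("bulk generator honours its trajectory contracts", {
  cfg <- deskConfig(rng_seed = 6L)
  bt <- simulateBulkTimecourse(cfg)
  tr <- simTruth(bt)
  cts <- assay(bt, "counts")
  design <- as.data.frame(colData(bt))
  stageMean <- function(genes, geno, st)
    mean(cts[genes, design$genotype == geno & design$stage == st]) /
      mean(tr$depth[design$genotype == geno & design$stage == st])
  # mutant Or-like collapse: D20 mean well below 0.2 x D15 mean
  expect_lt(stageMean(tr$or_like, "mutant", "D20"),
            0.2 * stageMean(tr$or_like, "mutant", "D15"))
  # early genes peak at D10 in both genotypes
  for (g in c("WT", "mutant")) {
    sm <- vapply(c("D10", "D15", "D20", "D25"),
                 function(st) stageMean(tr$early, g, st), 0)
    expect_identical(names(which.max(sm)), "D10")
  }
  # doubling depth on one sample doubles its size factor estimate
  cts2 <- cts
  cts2[, 1] <- cts2[, 1] * 2
  sf <- sizeFactorsMedianOfRatios(cts2)
  sf0 <- sizeFactorsMedianOfRatios(cts)
  expect_equal(unname(sf[1] / sf0[1] / (sf[2] / sf0[2])), 2,
               tolerance = 1e-6)
})

test_that("cluster-pair generator produces the documented scenarios", {
  # clean case: every best hit is the true partner by score and identity
  cp <- simulateClusterPair(30, 0, 0, seed = 1)
  sim <- cp$similarity
  for (a in cp$listA) {
    rows <- sim[sim$query == a, ]
    expect_identical(rows$subject[which.max(rows$bit_score)],
                     cp$truth$partner[[a]])
    expect_identical(rows$subject[which.max(rows$pct_identity)],
                     cp$truth$partner[[a]])
  }
  # truncated gene: top bit score points at the wrong gene, top identity
  # at the true partner
  cp2 <- simulateClusterPair(30, 0.2, 0, seed = 2)
  for (a in cp2$truth$truncated) {
    rows <- cp2$similarity[cp2$similarity$query == a, ]
    expect_false(identical(rows$subject[which.max(rows$bit_score)],
                           cp2$truth$partner[[a]]))
    expect_identical(rows$subject[which.max(rows$pct_identity)],
                     cp2$truth$partner[[a]])
  }
  # collapsed bookkeeping: exactly the collapsed genes lack a partner
  cp3 <- simulateClusterPair(100, 0, 0.05, seed = 3)
  expect_identical(names(cp3$truth$partner)[is.na(cp3$truth$partner)],
                   cp3$truth$collapsed)
  expect_length(cp3$truth$collapsed, 5)
  expect_length(cp3$listB, 95)
})
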