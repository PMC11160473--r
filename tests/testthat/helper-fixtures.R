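# Shared fixtures, built lazily once per test run.

.fixtureCache <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# The full study-condition run: 2000 cells/genotype, WT neuron mass 0.67,
# mutant neuron mass 0.12, complete sn + bulk + retained pipeline.
studyFixture <- function() getFixture("study", function() {
  cfg <- deskConfig(sim_neuron_mass_mut = 0.12, rng_seed = 42L)
  res <- runPipeline(cfg, stages = c("simulate", "qc", "embed", "call",
                                     "classify", "survival", "bulk",
                                     "retained"))
  res$truth <- simTruth(res$snData)
  res$truthCat <- res$truth$cells$category[
    match(colnames(res$snData), res$truth$cells$cell_id)]
  res
})

# Small sn run for unit tests.
smallFixture <- function() getFixture("small", function() {
  cfg <- deskConfig(sim_n_cells_per_genotype = 400, rng_seed = 7L)
  res <- runPipeline(cfg, stages = c("simulate", "qc", "embed", "call",
                                     "classify", "survival"))
  res$truth <- simTruth(res$snData)
  res
})

# Exchangeable-null dataset: no batch effect, used for type-I calibration
# of the calling procedure on housekeeping genes.
nullFixture <- function() getFixture("null", function() {
  cfg <- deskConfig(sim_n_cells_per_genotype = 1000, sim_batch_sdlog = 0,
                    rng_seed = 11L)
  runPipeline(cfg, stages = c("simulate", "qc", "embed", "call"))
})

# Brute-force one-sided Mann-Whitney oracle: enumerate every C(n+m, n)
# assignment of the pooled values; independent of the package's dynamic
# programming / merge implementation.
mwuOracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  uOf <- function(xs, ys)
    sum(vapply(xs, function(v) sum(ys < v) + 0.5 * sum(ys == v), 0))
  uObs <- uOf(x, y)
  combs <- utils::combn(length(pool), n)
  us <- apply(combs, 2, function(idx) uOf(pool[idx], pool[-idx]))
  mean(us >= uObs - 1e-9)
}

# minimal hand-made AntennalExperiment for unit tests
toyExperiment <- function(counts, classes = NULL, genotype = NULL) {
  nG <- nrow(counts)
  nC <- ncol(counts)
  if (is.null(classes)) classes <- rep("other", nG)
  anno <- data.frame(gene_id = sprintf("g%03d", seq_len(nG)),
                     gene_class = classes, scaffold = "s1",
                     start = seq_len(nG) * 1000,
                     end = seq_len(nG) * 1000 + 500, strand = "+",
                     stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = sprintf("c%03d", seq_len(nC)),
                     library_id = "lib1",
                     genotype = if (is.null(genotype)) rep("WT", nC)
                     else genotype,
                     stringsAsFactors = FALSE)
  AntennalExperiment(as.matrix(counts), meta, anno)
}
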