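#' Desk-scale antennal gene universe
#'
#' Builds the default 1200-gene annotation used by the synthetic datasets:
#' 300 tuning Or genes in 12 tandem clusters of 25, the single co-receptor
#' \code{orco}, the four Ir co-receptors (Ir8a, Ir25a.1, Ir25a.2, Ir76b),
#' 20 tuning Irs, 10 Grs, the ammonia transporter Rh50 and mechanoreceptor
#' nompC, the neuron / glia / muscle / epithelium / support marker genes,
#' 30 mitochondrial genes, and background genes. Ten "leaky driver"
#' background genes sit immediately next to one Or gene in each of the
#' first ten Or clusters; those Ors are the ones the nonneuronal programs
#' express. Coordinates are 1-based inclusive.
#'
#' @return a data.frame with columns \code{gene_id}, \code{gene_class},
#'   \code{scaffold}, \code{start}, \code{end}, \code{strand}.
#' @export
antennalGeneUniverse <- function() {
  rows <- list()
  add <- function(id, cls, scf, start, len = 2000, strand = "+")
    data.frame(gene_id = id, gene_class = cls, scaffold = scf,
               start = start, end = start + len - 1, strand = strand,
               stringsAsFactors = FALSE)
  # 12 tandem Or clusters of 25 genes
  orIds <- sprintf("Or%03d", 1:300)
  orCl <- rep(1:12, each = 25)
  orPos <- rep(1:25, times = 12)
  rows$or <- add(orIds, "tuning_Or", sprintf("scf_or_%02d", orCl),
                 10000 + (orPos - 1) * 5000)
  # leaky neighbor genes next to the 25th Or of clusters 1..10
  retained <- sprintf("Or%03d", seq(25, 250, by = 25))
  rows$nbg <- add(sprintf("nbg%02d", 1:10), "other",
                  sprintf("scf_or_%02d", 1:10), 132500, len = 1200)
  rows$irco <- add(c("Ir8a", "Ir25a.1", "Ir25a.2", "Ir76b"), "irco",
                   "scf_ir", seq(10000, by = 10000, length.out = 4))
  rows$ir <- add(sprintf("Ir%03d", 1:20), "tuning_Ir", "scf_ir",
                 seq(100000, by = 5000, length.out = 20))
  rows$gr <- add(sprintf("Gr%03d", 1:10), "Gr", "scf_gr",
                 seq(10000, by = 5000, length.out = 10))
  misc <- data.frame(
    gene_id = c("orco", "Rh50", "nompC", "nSyb", "fne", "Syt1", "onecut",
                "repo", "Mhc", "grh", "sv"),
    gene_class = c("orco", "Rh50", "nompC", rep("neuron_marker", 4),
                   "glia_marker", "muscle_marker", "epithelium_marker",
                   "support_marker"),
    stringsAsFactors = FALSE)
  rows$misc <- add(misc$gene_id, misc$gene_class, "scf_misc",
                   seq(10000, by = 10000, length.out = nrow(misc)))
  rows$mito <- add(sprintf("mt%02d", 1:30), "mito", "scf_mt",
                   seq(1000, by = 2000, length.out = 30), len = 1000)
  rows$bg <- add(sprintf("bg%03d", 1:815), "other",
                 sprintf("scf_bg_%02d", rep(1:8, length.out = 815)),
                 10000 + 8000 * (seq_len(815) - 1) %/% 8)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default cell programs
#'
#' The receptor-coexpression program templates behind the synthetic
#' antennal dataset. Each program is one simulated cell type: a category
#' label, a mixture weight (wild-type), a mutant survival probability, and
#' the set of genes it expresses with their mean UMI at unit depth.
#' Receptor combinations mirror the categories the analysis classifies
#' (OrX+orco, OrX+orco+Gr, OrX+orco+irco, orco+Ir+irco, orco only, Ir+irco,
#' Gr only, Gr/Ir with co-receptor, mechanosensory, ammonia Rh50) plus the
#' four nonneuronal types. ORN programs that express a tuning Or with orco
#' but no functional Ir complex have near-zero mutant survival; ORNs with
#' tuning Ir plus irco, non-Or neurons and nonneuronal cells survive fully.
#' Wild-type neuron mass is 0.67; the surviving programs carry 0.109 of it
#' and the dying programs retain 1\% residual survival, so the expected
#' mutant neuron mass under pure survival ablation is 0.12 and fully
#' surviving categories keep the same within-genotype fraction in both
#' genotypes (expected mutant/WT fraction ratio 1). Each program
#' additionally expresses a private 20-gene module (mean 2.5) so cell
#' types are separable in latent space; every program has clearly more
#' cells than the neighborhood size at the default scale, which a
#' kNN-graph clustering needs to resolve it.
#'
#' @param geneAnno gene annotation, by default
#'   \code{\link{antennalGeneUniverse}()}.
#' @param dyingSurvival mutant survival probability of the Or/orco ORN
#'   programs (near zero; kept slightly positive so ablated Or genes retain
#'   a measurable mutant mean).
#' @return a list of program definitions (class \code{"cellPrograms"}).
#' @export
defaultPrograms <- function(geneAnno = antennalGeneUniverse(),
                            dyingSurvival = 0.01) {
  neuron <- c(nSyb = 3, fne = 2.5, Syt1 = 3, onecut = 2)
  pr <- list()
  p <- function(name, category, class, weight, survival, means)
    list(name = name, category = category, class = class, weight = weight,
         survival = survival, means = means)
  for (i in 1:12)
    pr[[length(pr) + 1]] <- p(sprintf("OrX_orco.%02d", i), "OrX_orco",
                              "neuron", 0.035, dyingSurvival,
                              c(neuron, orco = 6,
                                stats::setNames(3, sprintf("Or%03d", i))))
  for (i in 1:2)
    pr[[length(pr) + 1]] <- p(sprintf("OrX_orco_Gr.%d", i), "OrX_orco_Gr",
                              "neuron", 0.025, dyingSurvival,
                              c(neuron, orco = 6,
                                stats::setNames(c(3, 2.5),
                                                c(sprintf("Or%03d", 12 + i),
                                                  sprintf("Gr%03d", i)))))
  for (i in 1:2)
    pr[[length(pr) + 1]] <- p(sprintf("OrX_orco_irco.%d", i),
                              "OrX_orco_irco", "neuron", 0.0255,
                              dyingSurvival,
                              c(neuron, orco = 6, Ir8a = 3,
                                stats::setNames(3, sprintf("Or%03d", 14 + i))))
  pr[[length(pr) + 1]] <- p("orco_only", "orco_only", "neuron", 0.04,
                            dyingSurvival, c(neuron, orco = 6))
  pr[[length(pr) + 1]] <- p("orco_Ir_irco.1", "orco_Ir_irco", "neuron",
                            0.02, 1,
                            c(neuron, orco = 6, Ir001 = 3, Ir8a = 2.5,
                              Ir76b = 2.5))
  pr[[length(pr) + 1]] <- p("orco_Ir_irco.2", "orco_Ir_irco", "neuron",
                            0.02, 1, c(neuron, orco = 6, Ir002 = 3,
                                        Ir8a = 3))
  for (i in 1:3) {
    m <- c(neuron, stats::setNames(3, sprintf("Ir%03d", 2 + i)),
           `Ir25a.1` = 3, Ir76b = 2.5)
    if (i == 3) m <- c(m, `Ir25a.2` = 2)
    pr[[length(pr) + 1]] <- p(sprintf("Ir_irco.%d", i), "Ir_irco",
                              "neuron", 0.008, 1, m)
  }
  for (i in 1:2)
    pr[[length(pr) + 1]] <- p(sprintf("Gr_only.%d", i), "Gr_only",
                              "neuron", 0.0065, 1,
                              c(neuron, stats::setNames(3, sprintf("Gr%03d", 2 + i))))
  pr[[length(pr) + 1]] <- p("Gr_Ir_coreceptor", "Gr_Ir_coreceptor",
                            "neuron", 0.009, 1,
                            c(neuron, Gr005 = 3, `Ir25a.2` = 3, Ir76b = 2))
  pr[[length(pr) + 1]] <- p("mechanosensory", "mechanosensory", "neuron",
                            0.015, 1, c(neuron, nompC = 4))
  pr[[length(pr) + 1]] <- p("ammonia_Rh50", "ammonia_Rh50", "neuron",
                            0.008, 1, c(neuron, Rh50 = 4))
  # nonneuronal; support and epithelium carry the "retained" Or genes plus
  # their leaky neighbor drivers
  supOr <- stats::setNames(rep(1.5, 10),
                           c(sprintf("Or%03d", seq(25, 125, by = 25)),
                             sprintf("nbg%02d", 1:5)))
  epiOr <- stats::setNames(rep(1.5, 10),
                           c(sprintf("Or%03d", seq(150, 250, by = 25)),
                             sprintf("nbg%02d", 6:10)))
  pr[[length(pr) + 1]] <- p("glia", "glia", "nonneuronal", 0.10, 1,
                            c(repo = 4))
  pr[[length(pr) + 1]] <- p("support", "support", "nonneuronal", 0.10, 1,
                            c(sv = 4, supOr))
  pr[[length(pr) + 1]] <- p("epithelium", "epithelium", "nonneuronal",
                            0.08, 1, c(grh = 4, epiOr))
  pr[[length(pr) + 1]] <- p("muscle", "muscle", "nonneuronal", 0.05, 1,
                            c(Mhc = 4))
  names(pr) <- vapply(pr, `[[`, "", "name")
  badGene <- setdiff(unlist(lapply(pr, function(x) names(x$means))),
                     geneAnno$gene_id)
  if (length(badGene))
    stop("program genes absent from annotation: ",
         paste(badGene, collapse = ", "))
  structure(pr, class = "cellPrograms", geneAnno = geneAnno)
}

#' Simulate an antennal single-nucleus dataset with known truth
#'
#' Draws sparse negative-binomial UMI counts for a mixture of receptor
#' programs under a wild-type and a co-receptor-mutant genotype. Each cell
#' gets a log-normal depth factor; counts for gene g are negative binomial
#' with mean depth x program mean and variance mu + dispersion x mu^2
#' (Poisson when \code{sim_dispersion = 0}). Mutant cells are drawn from
#' the program mixture after applying each program's survival probability:
#' neuron programs keep mass weight x survival (renormalised to the mutant
#' neuron mass), and nonneuronal programs absorb the freed mass in
#' proportion to their wild-type weights. Mitochondrial genes are emitted
#' so the mitochondrial read percentage is controllable (about 0.5\% with a
#' small contaminated tail), and the second wild-type library carries a
#' multiplicative per-gene log-normal batch factor.
#'
#' @param config a \code{PipelineConfig}; the \code{sim_*} keys are the
#'   study conditions (see \code{\link{deskConfig}}).
#' @param programs program set from \code{\link{defaultPrograms}}; mixture
#'   weights must sum to 1.
#' @param nCellsPerGenotype cells per genotype (default from config).
#' @param seed RNG seed (default from config).
#' @return an \linkS4class{AntennalExperiment}; \code{simTruth()} on the
#'   result returns the generator's ground truth (per-cell program and
#'   category, per-program expressed receptor sets, retained and ablated
#'   Or gene lists).
#' @export
simulateAntennalSn <- function(config = deskConfig(),
                               programs = defaultPrograms(),
                               nCellsPerGenotype = config$sim_n_cells_per_genotype,
                               seed = config$rng_seed) {
  anno <- attr(programs, "geneAnno")
  w <- vapply(programs, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop("program mixture weights must sum to 1 (got ", signif(sum(w), 6), ")")
  s <- vapply(programs, `[[`, 0, "survival")
  if (any(s < 0 | s > 1)) stop("survival probabilities must lie in [0, 1]")
  isNeuron <- vapply(programs, `[[`, "", "class") == "neuron"

  massWT <- config$sim_neuron_mass_wt
  wWT <- w
  wWT[isNeuron] <- w[isNeuron] / sum(w[isNeuron]) * massWT
  wWT[!isNeuron] <- w[!isNeuron] / sum(w[!isNeuron]) * (1 - massWT)
  survMean <- sum(wWT[isNeuron] * s[isNeuron]) / massWT
  massMut <- config$sim_neuron_mass_mut
  if (is.na(massMut)) massMut <- massWT * survMean
  wMUT <- wWT
  neuronMass <- sum(wWT[isNeuron] * s[isNeuron])
  wMUT[isNeuron] <- if (neuronMass > 0)
    wWT[isNeuron] * s[isNeuron] / neuronMass * massMut else 0
  wMUT[!isNeuron] <- wWT[!isNeuron] / sum(wWT[!isNeuron]) * (1 - massMut)

  nGenes <- nrow(anno)
  geneIdx <- stats::setNames(seq_len(nGenes), anno$gene_id)
  receptorGenes <- anno$gene_id[anno$gene_class %in% RECEPTOR_CLASSES]
  mitoIdx <- which(anno$gene_class == "mito")
  bgIds <- anno$gene_id[anno$gene_class == "other" &
                          !startsWith(anno$gene_id, "nbg")]
  nProg <- length(programs)
  moduleGenes <- split(bgIds[seq_len(20 * nProg)], rep(seq_len(nProg), each = 20))
  hkIds <- bgIds[-seq_len(20 * nProg)]

  out <- withSeed(stageSeed(seed, "simulate_sn"), {
    hkMeans <- stats::setNames(stats::rgamma(length(hkIds), shape = 0.6,
                                             scale = 2.5), hkIds)
    # per-program base mean vectors at unit depth
    baseMeans <- matrix(0, nGenes, nProg,
                        dimnames = list(anno$gene_id, names(programs)))
    baselineIds <- setdiff(anno$gene_id[anno$gene_class == "other"], hkIds)
    for (pIdx in seq_len(nProg)) {
      mu <- numeric(nGenes)
      mu[geneIdx[hkIds]] <- hkMeans
      mu[geneIdx[baselineIds]] <- config$sim_baseline_noise
      mu[geneIdx[moduleGenes[[pIdx]]]] <- 2.5
      pm <- programs[[pIdx]]$means
      mu[geneIdx[names(pm)]] <- pm
      baseMeans[, pIdx] <- mu
    }
    batchFactor <- stats::rlnorm(nGenes, 0, config$sim_batch_sdlog)

    nWT <- nCellsPerGenotype
    nMUT <- nCellsPerGenotype
    progWT <- sample(nProg, nWT, replace = TRUE, prob = wWT)
    progMUT <- sample(nProg, nMUT, replace = TRUE, prob = wMUT)
    libWT <- sample(rep(c("wt1", "wt2"), length.out = nWT))
    prog <- c(progWT, progMUT)
    lib <- c(libWT, rep("mut1", nMUT))
    geno <- rep(c("WT", "mutant"), c(nWT, nMUT))
    nCells <- nWT + nMUT
    depth <- stats::rlnorm(nCells, 0, config$sim_depth_sdlog)
    contam <- stats::runif(nCells) < 0.02
    mitoFrac <- ifelse(contam,
                       stats::rbeta(nCells, 6, 144),
                       stats::rbeta(nCells, 1.5, 298.5))

    counts <- matrix(0L, nGenes, nCells)
    size <- if (config$sim_dispersion > 0) 1 / config$sim_dispersion else Inf
    for (pIdx in seq_len(nProg)) {
      for (lb in c("wt1", "wt2", "mut1")) {
        idx <- which(prog == pIdx & lib == lb)
        if (!length(idx)) next
        mu <- baseMeans[, pIdx]
        if (lb == "wt2") mu <- mu * batchFactor
        tot <- sum(mu[-mitoIdx])
        mm <- mu %o% depth[idx]
        mm[mitoIdx, ] <- rep(mitoFrac[idx] / (1 - mitoFrac[idx]) * tot / 30,
                             each = length(mitoIdx)) * rep(depth[idx],
                                                           each = length(mitoIdx))
        cts <- if (is.finite(size))
          stats::rnbinom(length(mm), size = size, mu = mm)
        else stats::rpois(length(mm), mm)
        counts[, idx] <- cts
      }
    }
    list(counts = counts, prog = prog, lib = lib, geno = geno)
  })

  cellId <- sprintf("cell%05d", seq_along(out$prog))
  meta <- data.frame(cell_id = cellId, library_id = out$lib,
                     genotype = out$geno, stringsAsFactors = FALSE)
  m <- methods::as(out$counts, "CsparseMatrix")
  ae <- AntennalExperiment(m, meta, anno)

  progNames <- names(programs)
  categories <- vapply(programs, `[[`, "", "category")
  classes <- vapply(programs, `[[`, "", "class")
  expressedReceptors <- lapply(programs, function(p)
    intersect(names(p$means), receptorGenes))
  orHost <- lapply(stats::setNames(nm = anno$gene_id[anno$gene_class == "tuning_Or"]),
                   function(g) progNames[vapply(programs, function(p)
                     g %in% names(p$means), TRUE)])
  expressedOr <- names(orHost)[lengths(orHost) > 0]
  retainedOr <- names(orHost)[vapply(orHost, function(h)
    length(h) > 0 && any(classes[h] == "nonneuronal"), TRUE)]
  ablatedOr <- names(orHost)[vapply(orHost, function(h)
    length(h) > 0 && all(classes[h] == "neuron" & s[h] <= 0.05), TRUE)]
  truth <- list(
    cells = data.frame(
      cell_id = cellId, program = progNames[out$prog],
      category = categories[out$prog],
      neuronal = classes[out$prog] == "neuron", stringsAsFactors = FALSE),
    expressed_receptors = expressedReceptors,
    categories = categories,
    survival = s,
    weights_wt = vapply(programs, `[[`, 0, "weight"),
    expressed_or = expressedOr,
    retained_or = retainedOr,
    ablated_or = ablatedOr,
    partner_of = stats::setNames(sprintf("nbg%02d", 1:10),
                                 sprintf("Or%03d", seq(25, 250, by = 25))),
    neuron_mass = c(WT = massWT, mutant = massMut))
  metadata(ae)$truth <- truth
  metadata(ae)$config <- unclass(config)
  ae
}

#' Ground truth of a simulated object
#'
#' @param x an object produced by one of the simulators.
#' @return the generator's truth tables (list), or NULL if absent.
#' @export
simTruth <- function(x) metadata(x)$truth
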