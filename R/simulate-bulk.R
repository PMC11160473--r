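#' Simulate a bulk developmental time course with known truth
#'
#' Generates gene counts for pupal stages D10, D15, D20 and D25 under
#' wild-type and co-receptor-mutant genotypes, with three temporal
#' programs plus Or-like genes: "early" genes peak at D10 and decay,
#' "intermediate" genes peak at D15, "late" genes rise and plateau at
#' D20-D25. Or-like genes follow the wild-type intermediate-to-plateau
#' shape in both genotypes up to D15, then in the mutant collapse to at
#' most 20\% of their peak. Counts are negative binomial around stage
#' means scaled by a per-sample log-normal depth factor. Tuning Or genes
#' from the single-nucleus gene universe are embedded so the two
#' platforms can be compared gene-by-gene: Ors hosted by dying ORN
#' programs get the collapsing trajectory, retained (nonneuronally
#' expressed) Ors get a flat genotype-independent trajectory, all other
#' Ors stay at zero.
#'
#' @param config a \code{PipelineConfig} (keys \code{bulk_*} are the study
#'   conditions).
#' @param geneAnno annotation from \code{\link{antennalGeneUniverse}} (for
#'   the embedded Or genes).
#' @param snTruth optional truth list from a \code{\link{simulateAntennalSn}}
#'   run, used to decide which Ors collapse and which are retained;
#'   defaults to the default-program truth.
#' @param seed RNG seed (default from config).
#' @return a \linkS4class{BulkTimecourse}; \code{simTruth()} returns the
#'   per-gene trajectory class and the stage-program gene lists.
#' @export
simulateBulkTimecourse <- function(config = deskConfig(),
                                   geneAnno = antennalGeneUniverse(),
                                   snTruth = NULL,
                                   seed = config$rng_seed) {
  if (is.null(snTruth)) {
    pr <- defaultPrograms(geneAnno)
    classes <- vapply(pr, `[[`, "", "class")
    s <- vapply(pr, `[[`, 0, "survival")
    orIds <- geneAnno$gene_id[geneAnno$gene_class == "tuning_Or"]
    host <- lapply(stats::setNames(nm = orIds), function(g)
      names(pr)[vapply(pr, function(p) g %in% names(p$means), TRUE)])
    retainedOr <- orIds[vapply(host, function(h)
      length(h) > 0 && any(classes[h] == "nonneuronal"), TRUE)]
    ablatedOr <- orIds[vapply(host, function(h)
      length(h) > 0 && all(classes[h] == "neuron" & s[h] <= 0.05), TRUE)]
  } else {
    retainedOr <- snTruth$retained_or
    ablatedOr <- snTruth$ablated_or
  }

  stages <- c("D10", "D15", "D20", "D25")
  reps <- config$bulk_replicates
  if (reps < 2)
    warning("fewer than 2 replicates per condition: downstream statistics ",
            "will be degraded")
  design <- expand.grid(replicate = seq_len(reps), genotype = c("WT", "mutant"),
                        stage = stages, stringsAsFactors = FALSE)
  design <- design[, c("stage", "genotype", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$stage, design$genotype,
                              design$replicate)

  profiles <- list(
    early        = c(D10 = 1.00, D15 = 0.40, D20 = 0.15, D25 = 0.08),
    intermediate = c(D10 = 0.35, D15 = 1.00, D20 = 0.45, D25 = 0.30),
    late         = c(D10 = 0.08, D15 = 0.30, D20 = 0.90, D25 = 1.00),
    or_like_wt   = c(D10 = 0.15, D15 = 1.00, D20 = 0.92, D25 = 0.95),
    or_like_mut  = c(D10 = 0.15, D15 = 1.00, D20 = 0.10, D25 = 0.06),
    flat         = c(D10 = 1.00, D15 = 1.00, D20 = 1.00, D25 = 1.00))

  nP <- config$bulk_n_per_program
  ids <- c(sprintf("early%03d", seq_len(nP)),
           sprintf("inter%03d", seq_len(nP)),
           sprintf("late%03d", seq_len(nP)),
           sprintf("flat%04d", seq_len(config$bulk_n_flat)))
  cls <- c(rep("early", nP), rep("intermediate", nP), rep("late", nP),
           rep("flat", config$bulk_n_flat))
  orIds <- geneAnno$gene_id[geneAnno$gene_class == "tuning_Or"]
  ids <- c(ids, orIds)
  cls <- c(cls, ifelse(orIds %in% ablatedOr, "or_like",
                       ifelse(orIds %in% retainedOr, "or_retained", "or_silent")))
  nGenes <- length(ids)

  out <- withSeed(stageSeed(seed, "simulate_bulk"), {
    peak <- stats::rlnorm(nGenes, log(300), 0.5)
    peak[cls == "or_silent"] <- 0
    lens <- round(stats::runif(nGenes, 500, 4000))
    depth <- stats::rlnorm(nrow(design), 0, config$bulk_depth_sdlog)
    counts <- matrix(0, nGenes, nrow(design))
    size <- if (config$bulk_dispersion > 0) 1 / config$bulk_dispersion else Inf
    for (j in seq_len(nrow(design))) {
      st <- design$stage[j]
      shape <- vapply(seq_len(nGenes), function(g) {
        switch(cls[g],
               early = profiles$early[[st]],
               intermediate = profiles$intermediate[[st]],
               late = profiles$late[[st]],
               flat = profiles$flat[[st]],
               or_retained = profiles$flat[[st]],
               or_silent = 0,
               or_like = if (design$genotype[j] == "WT")
                 profiles$or_like_wt[[st]] else profiles$or_like_mut[[st]])
      }, 0)
      mu <- depth[j] * peak * shape
      counts[, j] <- if (is.finite(size))
        stats::rnbinom(nGenes, size = size, mu = mu)
      else stats::rpois(nGenes, mu)
    }
    list(counts = counts, lens = lens, depth = depth)
  })

  geneInfo <- data.frame(gene_id = ids, length = out$lens,
                         trajectory_class = cls, stringsAsFactors = FALSE)
  bt <- BulkTimecourse(out$counts, design, geneInfo)
  metadata(bt)$truth <- list(
    trajectory_class = stats::setNames(cls, ids),
    early = ids[cls == "early"],
    intermediate = ids[cls == "intermediate"],
    late = ids[cls == "late"],
    or_like = ids[cls == "or_like"],
    or_retained = ids[cls == "or_retained"],
    depth = stats::setNames(out$depth, design$sample_id))
  metadata(bt)$config <- unclass(config)
  bt
}
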