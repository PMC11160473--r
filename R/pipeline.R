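#' Run the full analysis pipeline
#'
#' Chains the pipeline stages on single-nucleus, bulk and/or ID-transfer
#' inputs: \code{qc} (two-stage cell filtering), \code{embed} (HVG / PCA /
#' kNN / Leiden), \code{call} (cluster gating, background draw, per-cell
#' receptor calls), \code{classify} (category assignment), \code{survival}
#' (WT vs mutant tallies), \code{bulk} (size factors, trajectories, stage
#' gene sets, Or-only PCA), \code{retained} (cross-platform fold changes,
#' concordance, retained set, neighbor coexpression) and \code{lift}
#' (reciprocal best hits + synteny fill). Missing inputs are fine as long
#' as no requested stage needs them. All intermediate tables are written
#' as TSV under \code{outDir} together with the parameters actually used;
#' outputs are a pure function of (inputs, config including
#' \code{rng_seed}), so two runs with identical inputs are byte-identical.
#'
#' @param config a validated \code{PipelineConfig}.
#' @param snData an \linkS4class{AntennalExperiment}, or NULL.
#' @param bulkData a \linkS4class{BulkTimecourse}, or NULL.
#' @param pairData a list from \code{\link{simulateClusterPair}} (elements
#'   \code{listA}, \code{listB}, \code{similarity}), or NULL.
#' @param stages which stages to run; \code{"simulate"} generates any
#'   missing input from the config's study conditions.
#' @param outDir output directory, or NULL to skip writing.
#' @return invisible list with the per-stage results.
#' @export
runPipeline <- function(config = deskConfig(), snData = NULL,
                        bulkData = NULL, pairData = NULL,
                        stages = c("qc", "embed", "call", "classify",
                                   "survival"),
                        outDir = NULL) {
  config <- validateConfig(config)
  known <- c("simulate", "qc", "embed", "call", "classify", "survival",
             "bulk", "retained", "lift")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  snStages <- c("qc", "embed", "call", "classify", "survival")
  if ("retained" %in% stages) stages <- union(stages, c(snStages, "bulk"))
  stages <- known[known %in% stages]

  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  res <- list(config = config)
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(df, name) {
    if (!is.null(outDir)) writeTsv(df, file.path(outDir, name))
  }

  if ("simulate" %in% stages) runStage("simulate", {
    if (is.null(snData) && any(snStages %in% stages))
      snData <- simulateAntennalSn(config)
    if (is.null(bulkData) && "bulk" %in% stages)
      bulkData <- simulateBulkTimecourse(
        config, snTruth = if (!is.null(snData)) simTruth(snData) else NULL)
    if (is.null(pairData) && "lift" %in% stages)
      pairData <- simulateClusterPair(seed = config$rng_seed)
  })
  needs <- function(stage, input, what)
    if (stage %in% stages && is.null(input))
      stop("stage '", stage, "' requested but no ", what, " input provided")
  for (st in intersect(stages, snStages)) needs(st, snData, "single-nucleus")
  needs("bulk", bulkData, "bulk")
  needs("lift", pairData, "cluster-pair")

  if ("qc" %in% stages) runStage("qc", {
    snData <- computeCellQC(snData)
    f <- filterCells(snData, config, stage = config$qc_stage)
    snData <- f$object
    res$qc_log <- f$log
    emit(f$log, "qc_removal_log.tsv")
  })
  if ("embed" %in% stages) runStage("embed", {
    snData <- normalizeCP10kLog1p(snData, scale = config$cp10k_scale)
    res$embedding <- embedCells(snData, config)
    emit(data.frame(cell_id = colnames(snData),
                    cluster = clusterIds(res$embedding)), "clusters.tsv")
  })
  if ("call" %in% stages) runStage("call", {
    res$gating <- gateClusters(snData, res$embedding)
    res$background <- drawBackground(snData, res$gating$cellClass,
                                     size = config$background_size,
                                     seed = config$rng_seed)
    res$calls <- buildCallMatrix(snData, res$embedding, res$background,
                                 res$gating$cellClass,
                                 alpha = config$alpha)
    emit(data.frame(cell_id = rownames(calls(res$calls)),
                    as.data.frame(calls(res$calls) + 0L)), "calls.tsv")
    emit(data.frame(cell_id = rownames(pvals(res$calls)),
                    as.data.frame(pvals(res$calls))), "call_pvals.tsv")
  })
  if ("classify" %in% stages) runStage("classify", {
    res$categories <- assignCategories(res$calls, res$gating$cellClass,
                                       as.data.frame(rowData(snData)))
    emit(data.frame(cell_id = colnames(snData),
                    genotype = genotype(snData),
                    category = unname(res$categories)), "categories.tsv")
  })
  if ("survival" %in% stages) runStage("survival", {
    res$survival <- survivalTable(res$categories, genotype(snData))
    nf <- attr(res$survival, "neuron_fraction")
    emit(res$survival, "survival.tsv")
    emit(data.frame(genotype = names(nf), neuron_fraction = unname(nf)),
         "neuron_fraction.tsv")
  })
  if ("bulk" %in% stages) runStage("bulk", {
    sf <- sizeFactorsMedianOfRatios(assay(bulkData, "counts"))
    res$size_factors <- sf
    norm <- normalizeBulk(bulkData)
    design <- as.data.frame(colData(bulkData))
    orGenes <- grep("^Or[0-9]", rownames(bulkData), value = TRUE)
    expressedOr <- orGenes[rowSums(assay(bulkData, "counts")[orGenes, ,
                                                             drop = FALSE]) > 0]
    res$or_trajectory <- scaledTrajectory(norm, design, expressedOr)
    res$stage_sets <- stageGeneSets(bulkData,
                                    loadingSetSize = config$loading_set_size)
    if (length(expressedOr) >= 2)
      res$or_pca <- orPCA(bulkData, expressedOr)
    emit(data.frame(sample_id = names(sf), size_factor = unname(sf)),
         "size_factors.tsv")
    emit(res$or_trajectory$summary, "or_trajectory.tsv")
    emit(data.frame(
      gene_id = c(res$stage_sets$early, res$stage_sets$intermediate,
                  res$stage_sets$late),
      set = rep(c("early", "intermediate", "late"),
                c(length(res$stage_sets$early),
                  length(res$stage_sets$intermediate),
                  length(res$stage_sets$late)))), "stage_gene_sets.tsv")
  })
  if ("retained" %in% stages) runStage("retained", {
    orGenes <- rownames(snData)[rowData(snData)$gene_class == "tuning_Or"]
    res$fc_records <- crossPlatformFC(snData, bulkData, orGenes,
                                      cp10kScale = config$cp10k_scale)
    res$concordance <- concordance(res$fc_records)
    res$retained <- selectRetained(res$fc_records,
                                   cutoffSn = config$fc_cutoff_sn,
                                   cutoffBulk = config$fc_cutoff_bulk)
    nonneur <- names(res$gating$cellClass)[res$gating$cellClass != "neuronal"]
    res$coexpression <- neighborCoexpression(snData, nonneur, res$retained)
    emit(res$fc_records, "fold_changes.tsv")
    emit(res$coexpression, "coexpression.tsv")
    if (!is.null(outDir))
      writeLines(res$retained, file.path(outDir, "retained_or.txt"))
  })
  if ("lift" %in% stages) runStage("lift", {
    rbh <- reciprocalBestHits(pairData$similarity)
    res$assignments <- syntenyFill(rbh, pairData$listA, pairData$listB,
                                   pairData$similarity,
                                   gapPenalty = config$gap_penalty,
                                   minIdentity = config$min_identity)
    res$transfer_report <- transferReport(res$assignments)
    emit(res$assignments, "id_assignments.tsv")
  })
  res$snData <- snData
  res$bulkData <- bulkData
  if (!is.null(outDir))
    writeConfig(config, file.path(outDir, "params_used.yaml"))
  invisible(res)
}
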