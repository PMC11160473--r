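#' Compute per-cell QC fields
#'
#' Adds \code{n_genes_detected} (genes with nonzero count),
#' \code{n_umis} (total counts) and \code{pct_mito} (percentage of counts
#' from genes of class \code{mito}) to the cell metadata.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @return the object with updated \code{colData}.
#' @export
computeCellQC <- function(ae) {
  cts <- assay(ae, "counts")
  mito <- rowData(ae)$gene_class == "mito"
  tot <- Matrix::colSums(cts)
  cd <- colData(ae)
  cd$n_genes_detected <- Matrix::colSums(cts > 0)
  cd$n_umis <- tot
  cd$pct_mito <- ifelse(tot > 0, 100 * Matrix::colSums(cts[mito, , drop = FALSE]) / tot, 0)
  colData(ae) <- cd
  ae
}

#' Two-stage cell filtering
#'
#' Stage 1 (lenient) removes cells with fewer than \code{qc1_min_genes}
#' detected genes, more than \code{qc1_max_umis} UMIs, or more than
#' \code{qc1_max_pct_mito} percent mitochondrial counts. The stringent
#' stage additionally removes cells exceeding \code{qc2_max_genes} detected
#' genes, \code{qc2_max_umis} UMIs or \code{qc2_max_pct_mito} percent
#' mitochondrial counts. All inequalities are strict, so a cell exactly at
#' a bound is kept. Filtering is idempotent.
#'
#' @param ae an \linkS4class{AntennalExperiment} with QC fields (see
#'   \code{\link{computeCellQC}}).
#' @param config a \code{PipelineConfig} carrying the thresholds.
#' @param stage \code{"lenient"} (stage 1 only) or \code{"stringent"}
#'   (stages 1 and 2).
#' @return a list with \code{object} (the filtered experiment) and
#'   \code{log} (data.frame \code{cell_id}, \code{rule}: which rule(s)
#'   fired for each removed cell).
#' @export
filterCells <- function(ae, config = deskConfig(),
                        stage = config$qc_stage) {
  if (!stage %in% c("lenient", "stringent"))
    stop("unknown QC stage: '", stage, "'")
  cd <- colData(ae)
  if (!all(c("n_genes_detected", "n_umis", "pct_mito") %in% colnames(cd)))
    ae <- computeCellQC(ae)
  cd <- colData(ae)
  rules <- list(
    min_genes = cd$n_genes_detected < config$qc1_min_genes,
    max_umis = cd$n_umis > config$qc1_max_umis,
    max_pct_mito = cd$pct_mito > config$qc1_max_pct_mito)
  if (stage == "stringent")
    rules <- c(rules, list(
      max_genes_stringent = cd$n_genes_detected > config$qc2_max_genes,
      max_umis_stringent = cd$n_umis > config$qc2_max_umis,
      max_pct_mito_stringent = cd$pct_mito > config$qc2_max_pct_mito))
  fired <- do.call(cbind, rules)
  remove <- rowSums(fired) > 0
  logDf <- data.frame(
    cell_id = cd$cell_id[remove],
    rule = apply(fired[remove, , drop = FALSE], 1, function(r)
      paste(names(rules)[r], collapse = ";")),
    stringsAsFactors = FALSE)
  list(object = ae[, !remove], log = logDf)
}

#' Remove named rRNA genes
#'
#' Drops the listed genes (e.g. large-subunit ribosomal RNA annotations)
#' from the matrix; all other genes are untouched. IDs absent from the
#' matrix are tolerated with a log message.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @param rrnaIds character vector of gene ids to drop (possibly empty).
#' @return the experiment without the named genes.
#' @export
removeRrnaGenes <- function(ae, rrnaIds = character()) {
  if (!length(rrnaIds)) return(ae)
  absent <- setdiff(rrnaIds, rownames(ae))
  if (length(absent))
    logMsg("rRNA ids not present in matrix (ignored): ",
           paste(absent, collapse = ", "))
  keep <- !(rownames(ae) %in% rrnaIds)
  ae[keep, ]
}
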