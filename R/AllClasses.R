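#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<- rowData rowData<- rowRanges
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

GENE_CLASSES <- c("tuning_Or", "orco", "tuning_Ir", "irco", "Gr", "Rh50",
                  "nompC", "neuron_marker", "glia_marker", "muscle_marker",
                  "epithelium_marker", "support_marker", "mito", "other")

RECEPTOR_CLASSES <- c("tuning_Or", "orco", "tuning_Ir", "irco", "Gr",
                      "Rh50", "nompC")

NONNEURONAL_LABELS <- c("glia", "muscle", "epithelium", "support",
                        "other_nonneuronal")

#' Antennal single-nucleus experiment
#'
#' A \linkS4class{SingleCellExperiment} holding a sparse UMI count matrix
#' (genes in rows, nuclei in columns) together with the cell metadata and
#' gene annotation this package's pipeline expects: per-cell
#' \code{library_id} and \code{genotype} (\code{"WT"} or \code{"mutant"}),
#' and per-gene \code{gene_class} (receptor taxonomy: tuning Or, orco,
#' tuning Ir, irco, Gr, Rh50, nompC, the cell-class markers, mitochondrial
#' and other genes) plus 1-based inclusive genomic coordinates.
#'
#' @slot .. no additional slots; the class exists for validity checking and
#'   method dispatch.
#' @export
setClass("AntennalExperiment", contains = "SingleCellExperiment")

setValidity("AntennalExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  rd <- rowData(object)
  need_cd <- c("cell_id", "library_id", "genotype")
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  else {
    if (anyDuplicated(cd$cell_id)) msg <- c(msg, "cell_id values must be unique")
    if (!all(cd$genotype %in% c("WT", "mutant")))
      msg <- c(msg, "genotype must be 'WT' or 'mutant'")
  }
  need_rd <- c("gene_id", "gene_class")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  else {
    if (anyDuplicated(rd$gene_id)) msg <- c(msg, "gene_id values must be unique")
    if (!all(rd$gene_class %in% GENE_CLASSES))
      msg <- c(msg, "unknown gene_class value")
  }
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (min(cts) < 0) msg <- c(msg, "counts must be nonnegative")
  }
  if ("pct_mito" %in% colnames(cd) &&
      (any(cd$pct_mito < 0) || any(cd$pct_mito > 100)))
    msg <- c(msg, "pct_mito must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct an AntennalExperiment
#'
#' @param counts gene x cell matrix (dense or \code{dgCMatrix}) of
#'   nonnegative integer UMI counts.
#' @param cellMeta data.frame with columns \code{cell_id}, \code{library_id},
#'   \code{genotype}; rows in the column order of \code{counts}.
#' @param geneAnno data.frame with columns \code{gene_id}, \code{gene_class},
#'   \code{scaffold}, \code{start}, \code{end}, \code{strand}; rows in the
#'   row order of \code{counts}.
#' @param computeQC add the derived per-cell QC fields (detected genes, UMI
#'   total, mitochondrial percentage) with \code{\link{computeCellQC}}.
#' @return an \linkS4class{AntennalExperiment}.
#' @export
AntennalExperiment <- function(counts, cellMeta, geneAnno, computeQC = TRUE) {
  if (ncol(counts) != nrow(cellMeta))
    stop("counts has ", ncol(counts), " cells but cellMeta has ",
         nrow(cellMeta), " rows")
  if (nrow(counts) != nrow(geneAnno))
    stop("counts has ", nrow(counts), " genes but geneAnno has ",
         nrow(geneAnno), " rows")
  if (any(geneAnno$start > geneAnno$end))
    stop("gene start must be <= end (1-based inclusive coordinates)")
  if (!all(geneAnno$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  rownames(counts) <- geneAnno$gene_id
  colnames(counts) <- cellMeta$cell_id
  gr <- GRanges(seqnames = geneAnno$scaffold,
                ranges = IRanges(start = geneAnno$start,
                                 end = geneAnno$end),
                strand = geneAnno$strand)
  mcols(gr) <- DataFrame(gene_id = geneAnno$gene_id,
                         gene_class = geneAnno$gene_class)
  names(gr) <- geneAnno$gene_id
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cellMeta, row.names = cellMeta$cell_id),
    rowRanges = gr)
  ae <- methods::new("AntennalExperiment", sce)
  if (computeQC) ae <- computeCellQC(ae)
  ae
}

#' Flat gene annotation table of an AntennalExperiment
#'
#' Reassembles the per-gene annotation (id, class, scaffold, 1-based
#' inclusive coordinates, strand) from the object's \code{rowRanges}.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @return a data.frame with columns \code{gene_id}, \code{gene_class},
#'   \code{scaffold}, \code{start}, \code{end}, \code{strand}.
#' @export
geneAnnotation <- function(ae) {
  gr <- rowRanges(ae)
  data.frame(gene_id = mcols(gr)$gene_id,
             gene_class = mcols(gr)$gene_class,
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Bulk developmental time course
#'
#' A \linkS4class{SummarizedExperiment} of bulk RNA-seq gene counts (genes x
#' samples) with the sample design (\code{stage} among D10/D15/D20/D25/adult,
#' \code{genotype}, \code{replicate}) in \code{colData} and gene lengths in
#' \code{rowData}.
#' @export
setClass("BulkTimecourse", contains = "SummarizedExperiment")

setValidity("BulkTimecourse", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("sample_id", "stage", "genotype", "replicate")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (!all(cd$stage %in% c("D10", "D15", "D20", "D25", "adult")))
      msg <- c(msg, "stage must be one of D10, D15, D20, D25, adult")
    if (!all(cd$genotype %in% c("WT", "het", "mutant")))
      msg <- c(msg, "genotype must be WT, het or mutant")
    if (anyDuplicated(paste(cd$stage, cd$genotype, cd$replicate)))
      msg <- c(msg, "(stage, genotype, replicate) must be unique")
  }
  if (!"length" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain gene 'length'")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a BulkTimecourse
#'
#' @param counts gene x sample matrix of counts.
#' @param design data.frame with \code{sample_id}, \code{stage},
#'   \code{genotype}, \code{replicate}.
#' @param geneInfo data.frame with at least \code{gene_id} and \code{length}
#'   (transcript length in bases).
#' @return a \linkS4class{BulkTimecourse}.
#' @export
BulkTimecourse <- function(counts, design, geneInfo) {
  rownames(counts) <- geneInfo$gene_id
  colnames(counts) <- design$sample_id
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(design, row.names = design$sample_id),
    rowData = DataFrame(geneInfo, row.names = geneInfo$gene_id))
  methods::new("BulkTimecourse", se)
}

#' Per-cell receptor expression calls
#'
#' Boolean cells x receptor-genes "expressing" calls with the one-sided
#' Mann-Whitney p-value behind each call, the cutoff used, and the fixed
#' background cell set the neighborhoods were compared against.
#'
#' @slot calls logical cells x genes matrix, \code{pvals < alpha}.
#' @slot pvals numeric matrix of the same shape, values in [0, 1].
#' @slot alpha the p-value cutoff (0.05 in the reference procedure).
#' @slot background character vector of background cell ids.
#' @export
setClass("ReceptorCalls",
         representation(calls = "matrix", pvals = "matrix",
                        alpha = "numeric", background = "character"))

setValidity("ReceptorCalls", function(object) {
  msg <- character()
  if (!identical(dim(object@calls), dim(object@pvals)))
    msg <- c(msg, "calls and pvals must have identical dimensions")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0, 1)")
  if (any(object@pvals < 0) || any(object@pvals > 1))
    msg <- c(msg, "pvals must lie in [0, 1]")
  if (!identical(object@calls, object@pvals < object@alpha))
    msg <- c(msg, "calls must equal (pvals < alpha) elementwise")
  if (length(msg)) msg else TRUE
})

#' Latent embedding, neighbor graph and clustering of cells
#'
#' @slot latent cells x PCs matrix.
#' @slot neighbors cells x k matrix of 1-based neighbor indices (self
#'   excluded).
#' @slot clusters integer cluster id per cell, contiguous from 0.
#' @slot varExplained fraction of variance explained per PC.
#' @slot elbow suggested number of PCs from the explained-variance elbow.
#' @export
setClass("CellEmbedding",
         representation(latent = "matrix", neighbors = "matrix",
                        clusters = "integer", varExplained = "numeric",
                        elbow = "integer"))

setValidity("CellEmbedding", function(object) {
  msg <- character()
  n <- nrow(object@latent)
  if (nrow(object@neighbors) != n)
    msg <- c(msg, "neighbors must have one row per cell")
  if (length(object@clusters) != n)
    msg <- c(msg, "clusters must have one entry per cell")
  if (n > 0 && any(object@neighbors == seq_len(n)))
    msg <- c(msg, "neighbor lists must exclude self")
  if (length(object@clusters) &&
      !identical(sort(unique(object@clusters)),
                 seq(0L, max(object@clusters))))
    msg <- c(msg, "cluster ids must be contiguous from 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AntennalExperiment", function(object) {
  cat("AntennalExperiment:", nrow(object), "genes x", ncol(object), "cells\n")
  gt <- table(colData(object)$genotype)
  cat("  genotypes:", paste(names(gt), gt, sep = "=", collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

setMethod("show", "BulkTimecourse", function(object) {
  cat("BulkTimecourse:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- colData(object)
  cat("  stages:", paste(sort(unique(cd$stage)), collapse = ", "),
      "| genotypes:", paste(sort(unique(cd$genotype)), collapse = ", "), "\n")
})

setMethod("show", "ReceptorCalls", function(object) {
  cat("ReceptorCalls:", nrow(object@calls), "cells x", ncol(object@calls),
      "receptor genes (alpha =", object@alpha, ")\n")
  cat("  positive calls:", sum(object@calls), "| background cells:",
      length(object@background), "\n")
})

setMethod("show", "CellEmbedding", function(object) {
  cat("CellEmbedding:", nrow(object@latent), "cells,", ncol(object@latent),
      "PCs,", ncol(object@neighbors), "neighbors,",
      length(unique(object@clusters)), "clusters\n")
})
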