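#' Read a sparse count matrix with its index files
#'
#' Reads a MatrixMarket coordinate-integer matrix (genes x cells, the
#' CellRanger layout) plus one-ID-per-line gene and cell index files.
#'
#' @param pathMatrix path to the \code{.mtx} file.
#' @param pathCells path to the cell/barcode index file (one id per line).
#' @param pathGenes path to the gene index file (one id per line).
#' @return a \code{dgCMatrix} with genes in rows (named) and cells in
#'   columns (named), IDs attached in file order.
#' @export
readCountMatrix <- function(pathMatrix, pathCells, pathGenes) {
  m <- methods::as(Matrix::readMM(pathMatrix), "CsparseMatrix")
  cells <- readLines(pathCells)
  genes <- readLines(pathGenes)
  if (anyDuplicated(genes))
    stop("duplicated gene id in ", pathGenes, ": ",
         genes[duplicated(genes)][1])
  if (anyDuplicated(cells))
    stop("duplicated cell id in ", pathCells, ": ",
         cells[duplicated(cells)][1])
  if (nrow(m) != length(genes))
    stop("matrix has ", nrow(m), " rows but ", pathGenes, " lists ",
         length(genes), " genes")
  if (ncol(m) != length(cells))
    stop("matrix has ", ncol(m), " columns but ", pathCells, " lists ",
         length(cells), " cells")
  if (any(m@x < 0)) stop("negative entries in ", pathMatrix)
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a sparse count matrix with its index files
#'
#' Inverse of \code{\link{readCountMatrix}}; the round trip is bit-exact.
#'
#' @param m gene x cell matrix (coerced to sparse).
#' @param pathMatrix,pathCells,pathGenes output paths.
#' @return \code{pathMatrix}, invisibly.
#' @export
writeCountMatrix <- function(m, pathMatrix, pathCells, pathGenes) {
  Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"),
                              "generalMatrix"), pathMatrix)
  writeLines(colnames(m), pathCells)
  writeLines(rownames(m), pathGenes)
  invisible(pathMatrix)
}

#' Read / write cell metadata, gene annotation and other pipeline tables
#'
#' Plain TSV with a header row; \code{writeAnnotatedTsv} formats numbers
#' deterministically so identical inputs give byte-identical files.
#'
#' @param path file path.
#' @param df a data.frame.
#' @return \code{readAnnotatedTsv}: a data.frame; the writer returns the
#'   path invisibly.
#' @export
readAnnotatedTsv <- function(path) readTsv(path)

#' @rdname readAnnotatedTsv
#' @export
writeAnnotatedTsv <- function(df, path) writeTsv(df, path)

#' Save / load an AntennalExperiment as plain-text files
#'
#' Writes \code{matrix.mtx}, \code{cells.tsv}, \code{genes.tsv} (index
#' files), \code{cell_meta.tsv} and \code{gene_anno.tsv} under \code{dir}.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @param dir directory (created if needed).
#' @return \code{writeAntennalExperiment}: \code{dir}, invisibly;
#'   \code{readAntennalExperiment}: the reconstructed object.
#' @export
writeAntennalExperiment <- function(ae, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountMatrix(assay(ae, "counts"),
                   file.path(dir, "matrix.mtx"),
                   file.path(dir, "cells.tsv"),
                   file.path(dir, "genes.tsv"))
  writeTsv(as.data.frame(colData(ae)), file.path(dir, "cell_meta.tsv"))
  writeTsv(geneAnnotation(ae), file.path(dir, "gene_anno.tsv"))
  invisible(dir)
}

#' @rdname writeAntennalExperiment
#' @export
readAntennalExperiment <- function(dir) {
  m <- readCountMatrix(file.path(dir, "matrix.mtx"),
                       file.path(dir, "cells.tsv"),
                       file.path(dir, "genes.tsv"))
  meta <- readTsv(file.path(dir, "cell_meta.tsv"))
  anno <- readTsv(file.path(dir, "gene_anno.tsv"))
  if (!all(meta$cell_id == colnames(m)))
    stop("cell_meta.tsv does not match the cell index file")
  AntennalExperiment(m, meta, anno, computeQC = !"n_umis" %in% colnames(meta))
}

#' Read a pairwise similarity table
#'
#' BLAST outfmt-6-like TSV with columns \code{query}, \code{subject},
#' \code{pct_identity}, \code{aln_length}, \code{bit_score}.
#'
#' @param path file path.
#' @return a data.frame with the five columns above.
#' @export
readSimilarityTable <- function(path) {
  df <- readTsv(path)
  need <- c("query", "subject", "pct_identity", "aln_length", "bit_score")
  if (!all(need %in% colnames(df)))
    stop("similarity table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(df$query, df$subject)))
    stop("similarity table has more than one row for an ordered pair")
  if (any(!is.finite(df$bit_score)) || any(df$bit_score < 0))
    stop("bit scores must be finite and nonnegative")
  df
}
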