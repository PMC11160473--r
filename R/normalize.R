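#' CP10k depth normalization with log1p transform
#'
#' Scales each cell to \code{scale} (10,000) total counts and applies the
#' natural-log \code{log(1 + x)} transform; zero counts map to zero and the
#' transform is depth-invariant (scaling a cell's counts by a constant
#' leaves its normalized values unchanged).
#'
#' @param x an \linkS4class{AntennalExperiment} (the result gains a
#'   \code{"logcounts"} assay) or a gene x cell count matrix (a matrix of
#'   the same shape is returned).
#' @param scale counts-per-cell target (default 10,000).
#' @return same type as the input; errors on a zero-total cell (such cells
#'   must be removed by QC first).
#' @export
normalizeCP10kLog1p <- function(x, scale = 10000) {
  if (methods::is(x, "AntennalExperiment")) {
    cts <- assay(x, "counts")
    assay(x, "logcounts") <- normalizeCP10kLog1p(cts, scale)
    return(x)
  }
  tot <- Matrix::colSums(x)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(x)[tot == 0], 3), collapse = ", "))
  if (methods::is(x, "sparseMatrix")) {
    out <- methods::as(x, "CsparseMatrix")
    out@x <- log1p(scale * out@x / rep.int(tot, diff(out@p)))
    out
  } else {
    log1p(scale * sweep(x, 2, tot, "/"))
  }
}
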