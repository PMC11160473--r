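#' Batch-aware highly variable gene selection
#'
#' Within each batch, genes are ranked by standardized variance: the
#' variance of their log-normalized expression divided by a smoothed
#' mean-variance trend (a rolling median of the variances over genes
#' ordered by mean expression). Ranks are then combined across batches by
#' median rank and the top \code{nTop} genes returned, ties broken by gene
#' id order. Batches with fewer than 50 cells are excluded from the
#' ranking with a warning.
#'
#' @param logcounts gene x cell matrix of log-normalized expression.
#' @param nTop number of genes to select (2000 in the reference analysis;
#'   truncated with a warning if fewer genes exist).
#' @param batch factor/character of batch labels per cell (e.g. library id
#'   or genotype); a single batch if NULL.
#' @param window rolling-median window width for the trend (odd; shrunk
#'   for small gene sets).
#' @return character vector of selected gene ids.
#' @export
selectHVGs <- function(logcounts, nTop = 2000, batch = NULL, window = 101) {
  nGenes <- nrow(logcounts)
  if (is.null(batch)) batch <- rep("all", ncol(logcounts))
  if (nTop > nGenes) {
    warning("nTop (", nTop, ") exceeds available genes (", nGenes,
            "); selecting all")
    nTop <- nGenes
  }
  batches <- split(seq_len(ncol(logcounts)), batch)
  small <- names(batches)[lengths(batches) < 50]
  if (length(small) && length(batches) > length(small)) {
    warning("batch(es) with fewer than 50 cells excluded from HVG ranking: ",
            paste(small, collapse = ", "))
    batches <- batches[lengths(batches) >= 50]
  }
  rankMat <- vapply(batches, function(idx) {
    m <- logcounts[, idx, drop = FALSE]
    mu <- Matrix::rowMeans(m)
    v <- Matrix::rowMeans(m^2) - mu^2
    v <- v * length(idx) / max(1, length(idx) - 1)
    ord <- order(mu, rownames(logcounts))
    k <- min(window, if (nGenes %% 2 == 0) nGenes - 1 else nGenes)
    if (k %% 2 == 0) k <- k - 1
    trend <- numeric(nGenes)
    trend[ord] <- stats::runmed(v[ord], k, endrule = "median")
    std <- v / pmax(trend, 1e-10)
    rank(-std, ties.method = "average")
  }, numeric(nGenes))
  med <- apply(rankMat, 1, stats::median)
  ord <- order(med, rownames(logcounts))
  rownames(logcounts)[ord][seq_len(nTop)]
}
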