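#' One-sided Mann-Whitney test ("greater")
#'
#' Tests whether \code{x} is stochastically greater than \code{y} using the
#' rank-sum statistic \eqn{U = \sum_i (\#\{y < x_i\} + 0.5\,\#\{y = x_i\})}.
#' When the pooled sample has at most \code{maxExact} values the p-value is
#' exact, by exhaustive enumeration of all \eqn{C(n+m, n)} assignments of
#' the pooled values to the two groups (ties handled exactly); otherwise a
#' normal approximation with continuity and tie correction is used. A
#' fully tied pooled sample gives p = 1.
#'
#' @param x,y numeric samples (focal neighborhood and background).
#' @param maxExact pooled-size limit for the exact branch (default 12).
#' @return the one-sided p-value.
#' @export
mwuGreater <- function(x, y, maxExact = 12L) {
  .cpp_mwu_greater(as.numeric(x), as.numeric(y), as.integer(maxExact))
}

#' Call one gene in one cell
#'
#' The per-cell "expressing / not expressing" decision: the gene's
#' log-normalized expression over the focal cell's neighborhood (the focal
#' cell plus its graph neighbors) is compared against its expression over
#' the fixed background set with \code{\link{mwuGreater}}; the cell is
#' called expressing when p < alpha. Rank tests are invariant to monotone
#' transforms, so testing log-normalized values is equivalent to testing
#' CP10k.
#'
#' @param neighborhood numeric values over the focal cell's neighborhood
#'   (must be nonempty).
#' @param background numeric values over the background cells.
#' @param alpha p-value cutoff (0.05).
#' @return list with \code{p} and logical \code{call}.
#' @export
callGeneInCell <- function(neighborhood, background, alpha = 0.05) {
  if (!length(neighborhood)) stop("empty neighborhood")
  p <- mwuGreater(neighborhood, background, 12L)
  list(p = p, call = p < alpha)
}

#' Draw the fixed background set
#'
#' Uniformly samples, without replacement, \code{size} wild-type cells
#' classified nonneuronal (by cluster gating). One fixed set is reused for
#' every gene and every focal cell in a run, which keeps calls comparable
#' across genes.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @param cellClass per-cell class labels from \code{\link{gateClusters}}
#'   (values \code{"neuronal"} or nonneuronal labels).
#' @param size background size (100 in the reference procedure).
#' @param seed RNG seed.
#' @return character vector of background cell ids.
#' @export
drawBackground <- function(ae, cellClass, size = 100, seed = 1) {
  eligible <- colnames(ae)[genotype(ae) == "WT" & cellClass != "neuronal"]
  if (length(eligible) < size)
    stop("only ", length(eligible), " eligible WT nonneuronal cells; ",
         size, " required (short by ", size - length(eligible), ")")
  if (length(eligible) == size) return(eligible)
  withSeed(stageSeed(seed, "background"), sort(sample(eligible, size)))
}

#' Build the per-cell receptor call matrix
#'
#' Applies \code{\link{callGeneInCell}} to every neuronal cell and every
#' receptor gene (classes tuning Or, orco, tuning Ir, irco, Gr, plus Rh50
#' and nompC). Nonneuronal cells get all-false rows with p = 1 (they are
#' classified at cluster level). Deterministic given its inputs.
#'
#' @param ae an \linkS4class{AntennalExperiment} with a \code{logcounts}
#'   assay.
#' @param embedding a \linkS4class{CellEmbedding} for the neighbor graph.
#' @param background background cell ids from \code{\link{drawBackground}}.
#' @param cellClass per-cell class labels from \code{\link{gateClusters}}.
#' @param receptorGenes receptor gene ids; defaults to all genes of the
#'   receptor classes in the annotation. IDs absent from the matrix are
#'   skipped with a warning.
#' @param alpha p-value cutoff.
#' @return a \linkS4class{ReceptorCalls}.
#' @export
buildCallMatrix <- function(ae, embedding, background, cellClass,
                            receptorGenes = NULL, alpha = 0.05) {
  lc <- as.matrix(assay(ae, "logcounts"))
  if (is.null(receptorGenes))
    receptorGenes <- rownames(ae)[rowData(ae)$gene_class %in% RECEPTOR_CLASSES]
  absent <- setdiff(receptorGenes, rownames(lc))
  if (length(absent)) {
    warning("receptor gene(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
    receptorGenes <- setdiff(receptorGenes, absent)
  }
  focal <- which(cellClass == "neuronal")
  nbhd <- rbind(focal, t(neighborIndex(embedding)[focal, , drop = FALSE]))
  bgIdx <- match(background, colnames(ae))
  if (anyNA(bgIdx)) stop("background cell absent from the experiment")
  geneIdx <- match(receptorGenes, rownames(lc))
  pv <- matrix(1, ncol(ae), length(receptorGenes),
               dimnames = list(colnames(ae), receptorGenes))
  if (length(focal) && length(geneIdx))
    pv[focal, ] <- .cpp_call_pvals(lc, nbhd, as.integer(bgIdx),
                                   as.integer(geneIdx))
  methods::new("ReceptorCalls", calls = pv < alpha, pvals = pv,
               alpha = alpha, background = background)
}
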