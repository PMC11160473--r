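#' Median-of-ratios size factors
#'
#' The classic bulk RNA-seq normalization: the reference is the per-gene
#' geometric mean across samples (genes with any zero count excluded), and
#' each sample's factor is the median across genes of its count over the
#' reference. Because the reference is recomputed from the data, the
#' factors are exactly invariant under global rescaling of the matrix
#' (and doubling one sample's counts doubles its factor relative to every
#' other sample's).
#'
#' @param counts gene x sample count matrix (at least 2 samples).
#' @return named numeric vector of size factors.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("at least 2 samples required")
  allPos <- rowSums(counts <= 0) == 0
  if (!any(allPos))
    stop("no gene has nonzero counts in every sample; cannot form the ",
         "geometric-mean reference")
  lg <- log(counts[allPos, , drop = FALSE])
  ref <- rowMeans(lg)
  factors <- apply(lg, 2, function(x) exp(stats::median(x - ref)))
  stats::setNames(factors, colnames(counts))
}

#' Normalized bulk counts
#'
#' @param bt a \linkS4class{BulkTimecourse} or a count matrix.
#' @return counts divided column-wise by the median-of-ratios size factors.
#' @export
normalizeBulk <- function(bt) {
  counts <- if (methods::is(bt, "BulkTimecourse")) assay(bt, "counts") else bt
  sf <- sizeFactorsMedianOfRatios(counts)
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Fragments per kilobase per million mapped reads
#'
#' \code{fpkm = count x 1e9 / (length x total)}.
#'
#' @param counts gene x sample count matrix.
#' @param lengths transcript lengths in bases (> 0), one per gene.
#' @param totals per-sample mapped totals; defaults to column sums.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths, totals = colSums(as.matrix(counts))) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(totals <= 0)) stop("zero mapped total for a sample")
  counts * 1e9 / (lengths %o% totals)
}

#' Max-scaled developmental trajectory summary
#'
#' For each gene: average the normalized expression over replicates within
#' each (genotype, stage), then divide the profile by its maximum across
#' all (genotype, stage) combinations; then report mean and SD across
#' genes per (genotype, stage). Genes with all-zero profiles are dropped
#' with a log message. Scaled values always lie in [0, 1].
#'
#' @param normCounts normalized gene x sample matrix (see
#'   \code{\link{normalizeBulk}}).
#' @param design data.frame with \code{sample_id}, \code{stage},
#'   \code{genotype} matching the columns.
#' @param genes gene ids to summarize (nonempty).
#' @return list with \code{summary} (genotype, stage, mean, sd, n_genes)
#'   and \code{profiles} (the per-gene scaled matrix).
#' @export
scaledTrajectory <- function(normCounts, design, genes) {
  if (!length(genes)) stop("empty gene set")
  genes <- intersect(genes, rownames(normCounts))
  grp <- interaction(design$genotype, design$stage, drop = TRUE, sep = "|")
  m <- normCounts[genes, , drop = FALSE]
  agg <- t(apply(m, 1, function(x) tapply(x, grp, mean)))
  colnames(agg) <- levels(grp)
  mx <- apply(agg, 1, max)
  zero <- mx == 0
  if (any(zero))
    logMsg(sum(zero), " gene(s) with all-zero profiles dropped")
  agg <- agg[!zero, , drop = FALSE] / mx[!zero]
  parts <- strsplit(colnames(agg), "|", fixed = TRUE)
  summary <- data.frame(
    genotype = vapply(parts, `[`, "", 1),
    stage = vapply(parts, `[`, "", 2),
    mean = colMeans(agg),
    sd = apply(agg, 2, stats::sd),
    n_genes = nrow(agg),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, profiles = agg)
}

#' Stage-biased gene sets from PC loadings
#'
#' Whole-transcriptome PCA over samples on log(normalized + 1) values
#' (genes centered). PC signs are fixed so that PC1 sample scores
#' correlate positively with the early-stage indicator and intermediate
#' (D15-peaking) samples score negatively on PC2; "early" genes are then
#' the k largest positive PC1 loadings, "intermediate" the k largest
#' negative PC2 loadings, and "late" the k largest negative PC1 loadings
#' (k = \code{loadingSetSize}, 750 in the reference analysis). Sets are
#' made disjoint with priority early > intermediate > late.
#'
#' @param bt a \linkS4class{BulkTimecourse}.
#' @param loadingSetSize genes per set (auto-reduced with a warning when
#'   fewer genes are available).
#' @return list with \code{early}, \code{intermediate}, \code{late} gene
#'   id vectors, plus \code{scores} and \code{varExplained}.
#' @export
stageGeneSets <- function(bt, loadingSetSize = 750) {
  design <- as.data.frame(colData(bt))
  if (nrow(design) < 3) stop("at least 3 samples required")
  x <- t(log(normalizeBulk(bt) + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  stageRank <- match(design$stage, c("D10", "D15", "D20", "D25", "adult"))
  # orient PC1: early samples high
  if (stats::cor(pc$x[, 1], stageRank) > 0) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  # orient PC2: intermediate (D15) samples negative
  if (ncol(pc$x) >= 2 &&
      stats::cor(pc$x[, 2], as.numeric(design$stage == "D15")) > 0) {
    pc$x[, 2] <- -pc$x[, 2]
    pc$rotation[, 2] <- -pc$rotation[, 2]
  }
  k <- loadingSetSize
  nGenes <- nrow(pc$rotation)
  if (3 * k > nGenes) {
    k <- nGenes %/% 3
    warning("loadingSetSize reduced to ", k, " (only ", nGenes,
            " genes available)")
  }
  l1 <- pc$rotation[, 1]
  l2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] else
    stats::setNames(numeric(nGenes), names(l1))
  early <- names(sort(l1, decreasing = TRUE))[seq_len(k)]
  inter <- setdiff(names(sort(l2)), early)[seq_len(k)]
  late <- setdiff(names(sort(l1)), c(early, inter))[seq_len(k)]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(early = early, intermediate = inter, late = late,
       scores = pc$x, varExplained = ev)
}

#' PCA restricted to Or genes
#'
#' Sample coordinates from PCA on the Or genes only (log normalized + 1),
#' for plotting wild-type versus mutant developmental trajectories.
#'
#' @param bt a \linkS4class{BulkTimecourse}.
#' @param orGenes Or gene ids (at least 2).
#' @return list with \code{scores} (samples x PCs) and
#'   \code{varExplained}.
#' @export
orPCA <- function(bt, orGenes) {
  orGenes <- intersect(orGenes, rownames(bt))
  if (length(orGenes) < 2) stop("at least 2 Or genes required")
  x <- t(log(normalizeBulk(bt)[orGenes, , drop = FALSE] + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = pc$x, varExplained = pc$sdev^2 / sum(pc$sdev^2))
}
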