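#' Cross-platform fold changes for Or genes
#'
#' Per Or gene, log2(mutant mean / WT mean) computed independently on the
#' two platforms: single-nucleus means over CP10k across all cells of each
#' genotype, and bulk means over FPKM across samples of each genotype.
#' On each platform, only genes with nonzero expression in both genotypes
#' get a record (others are NA on that platform).
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @param bt a \linkS4class{BulkTimecourse}.
#' @param orGenes Or gene ids present on both platforms.
#' @param cp10kScale depth-normalization target (10,000).
#' @return data.frame with \code{gene_id}, platform means and
#'   \code{log2fc_sn}, \code{log2fc_bulk}; errors if no gene passes on
#'   either platform.
#' @export
crossPlatformFC <- function(ae, bt, orGenes, cp10kScale = 10000) {
  cts <- assay(ae, "counts")
  tot <- Matrix::colSums(cts)
  cp10k <- cts[intersect(orGenes, rownames(cts)), , drop = FALSE]
  cp10k <- Matrix::t(Matrix::t(cp10k) * (cp10kScale / tot))
  wt <- genotype(ae) == "WT"
  snWT <- Matrix::rowMeans(cp10k[, wt, drop = FALSE])
  snMUT <- Matrix::rowMeans(cp10k[, !wt, drop = FALSE])

  fk <- fpkm(assay(bt, "counts"), rowData(bt)$length)
  fk <- fk[intersect(orGenes, rownames(fk)), , drop = FALSE]
  bwt <- colData(bt)$genotype == "WT"
  bulkWT <- rowMeans(fk[, bwt, drop = FALSE])
  bulkMUT <- rowMeans(fk[, !bwt, drop = FALSE])

  out <- data.frame(gene_id = orGenes, stringsAsFactors = FALSE)
  out$mean_sn_WT <- snWT[orGenes]
  out$mean_sn_mut <- snMUT[orGenes]
  out$mean_bulk_WT <- bulkWT[orGenes]
  out$mean_bulk_mut <- bulkMUT[orGenes]
  out$log2fc_sn <- ifelse(out$mean_sn_WT > 0 & out$mean_sn_mut > 0,
                          log2(out$mean_sn_mut / out$mean_sn_WT), NA_real_)
  out$log2fc_bulk <- ifelse(out$mean_bulk_WT > 0 & out$mean_bulk_mut > 0,
                            log2(out$mean_bulk_mut / out$mean_bulk_WT),
                            NA_real_)
  if (all(is.na(out$log2fc_sn)) && all(is.na(out$log2fc_bulk)))
    stop("no Or gene has nonzero expression in both genotypes on either ",
         "platform")
  out
}

#' Cross-platform fold-change concordance
#'
#' Squared Pearson and Spearman correlations between the single-nucleus
#' and bulk log2 fold changes, over genes with records on both platforms
#' (ties handled by average ranks). The sign of the Pearson correlation is
#' reported separately since squaring discards it.
#'
#' @param records output of \code{\link{crossPlatformFC}}.
#' @return list with \code{pearson_r2}, \code{spearman_r2},
#'   \code{pearson_sign} and \code{n}; correlations are NA when either
#'   axis has zero variance.
#' @export
concordance <- function(records) {
  ok <- stats::complete.cases(records[, c("log2fc_sn", "log2fc_bulk")])
  x <- records$log2fc_sn[ok]
  y <- records$log2fc_bulk[ok]
  if (length(x) < 3) stop("fewer than 3 genes with records on both platforms")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r2 = NA_real_, spearman_r2 = NA_real_,
                pearson_sign = NA_real_, n = length(x)))
  pr <- stats::cor(x, y)
  sr <- stats::cor(rank(x), rank(y))
  list(pearson_r2 = pr^2, spearman_r2 = sr^2, pearson_sign = sign(pr),
       n = length(x))
}

#' Select Or genes retained in the mutant
#'
#' Genes whose log2 fold change is above the cutoff on both platforms
#' (defaults -1, i.e. fold change above 0.5x on both), sorted by the
#' smaller of the two fold changes, descending. Lowering the cutoffs can
#' only grow the set.
#'
#' @param records output of \code{\link{crossPlatformFC}}.
#' @param cutoffSn,cutoffBulk log2 cutoffs.
#' @return character vector of retained gene ids.
#' @export
selectRetained <- function(records, cutoffSn = -1, cutoffBulk = -1) {
  ok <- !is.na(records$log2fc_sn) & !is.na(records$log2fc_bulk) &
    records$log2fc_sn > cutoffSn & records$log2fc_bulk > cutoffBulk
  sel <- records[ok, ]
  sel$gene_id[order(-pmin(sel$log2fc_sn, sel$log2fc_bulk), sel$gene_id)]
}

#' Neighbor-gene coexpression of retained Or genes
#'
#' For each retained Or: the nearest non-Or gene on the same scaffold (by
#' gene midpoint distance, strand ignored), the Jaccard overlap between
#' the nonneuronal cells with nonzero counts for the Or and for the
#' neighbor, and the fraction of the Or's total expression found in
#' nonneuronal cells. A strong overlap at short distance is the signature
#' of leaky regulation by the neighbor's regulatory elements. An Or alone
#' on its scaffold gets a record with missing neighbor and distance.
#'
#' @param ae an \linkS4class{AntennalExperiment}.
#' @param nonneuronalCells cell ids classified nonneuronal.
#' @param retainedGenes retained Or gene ids.
#' @return data.frame with \code{or_gene_id}, \code{neighbor_gene_id},
#'   \code{distance}, \code{jaccard},
#'   \code{nonneuronal_fraction_of_or_expression}.
#' @export
neighborCoexpression <- function(ae, nonneuronalCells, retainedGenes) {
  anno <- geneAnnotation(ae)
  anno$mid <- (anno$start + anno$end) / 2
  cts <- assay(ae, "counts")
  nn <- colnames(ae) %in% nonneuronalCells
  rows <- lapply(retainedGenes, function(g) {
    gi <- anno[anno$gene_id == g, ]
    cand <- anno[anno$scaffold == gi$scaffold &
                   anno$gene_class != "tuning_Or", ]
    if (!nrow(cand))
      return(data.frame(or_gene_id = g, neighbor_gene_id = NA_character_,
                        distance = NA_real_, jaccard = NA_real_,
                        nonneuronal_fraction_of_or_expression =
                          nnFraction(cts, g, nn), stringsAsFactors = FALSE))
    d <- abs(cand$mid - gi$mid)
    nb <- cand$gene_id[order(d, cand$gene_id)][1]
    a <- cts[g, ] > 0 & nn
    b <- cts[nb, ] > 0 & nn
    uni <- sum(a | b)
    data.frame(or_gene_id = g, neighbor_gene_id = nb, distance = min(d),
               jaccard = if (uni > 0) sum(a & b) / uni else 0,
               nonneuronal_fraction_of_or_expression = nnFraction(cts, g, nn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

nnFraction <- function(cts, g, nn) {
  tot <- sum(cts[g, ])
  if (tot == 0) return(0)
  sum(cts[g, nn]) / tot
}
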