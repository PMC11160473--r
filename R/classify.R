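#' Default marker panel
#'
#' Cluster-gating markers: a cluster is neuronal only if it expresses all
#' four neuron markers simultaneously; nonneuronal clusters are then
#' labelled by single markers (glia, muscle, epithelium, support), first
#' match in that order.
#'
#' @return named list of marker gene id vectors.
#' @export
defaultMarkerPanel <- function()
  list(neuron = c("nSyb", "fne", "Syt1", "onecut"),
       glia = "repo", muscle = "Mhc", epithelium = "grh", support = "sv")

#' Gate clusters into major cell classes
#'
#' A cluster "expresses" a marker when at least \code{minFrac} of its
#' member cells have a nonzero count for it and the cluster's mean
#' log-normalized expression exceeds the overall mean for that gene. A
#' cluster is neuronal iff it expresses all four neuron markers; remaining
#' clusters are labelled glia, muscle, epithelium or support by their
#' single markers (same rule, first match in that order), and otherwise
#' "other_nonneuronal".
#'
#' @param ae an \linkS4class{AntennalExperiment} with \code{logcounts}.
#' @param embedding a \linkS4class{CellEmbedding} (cluster ids).
#' @param panel marker panel, see \code{\link{defaultMarkerPanel}}.
#' @param minFrac minimum fraction of nonzero cells (0.25).
#' @return list with \code{clusterClass} (label per cluster, named by
#'   cluster id) and \code{cellClass} (label per cell: \code{"neuronal"}
#'   or the nonneuronal label).
#' @export
gateClusters <- function(ae, embedding, panel = defaultMarkerPanel(),
                         minFrac = 0.25) {
  cl <- clusterIds(embedding)
  cts <- assay(ae, "counts")
  lc <- assay(ae, "logcounts")
  markerIds <- unique(unlist(panel))
  missing <- setdiff(markerIds, rownames(ae))
  if (length(missing))
    stop("marker gene(s) absent from the experiment: ",
         paste(missing, collapse = ", "))
  overallMean <- Matrix::rowMeans(lc[markerIds, , drop = FALSE])
  clusters <- sort(unique(cl))
  clusterClass <- stats::setNames(character(length(clusters)),
                                  as.character(clusters))
  for (k in clusters) {
    idx <- which(cl == k)
    if (!length(idx)) stop("empty cluster ", k, " (upstream bug)")
    frac <- Matrix::rowMeans(cts[markerIds, idx, drop = FALSE] > 0)
    mn <- Matrix::rowMeans(lc[markerIds, idx, drop = FALSE])
    expresses <- frac >= minFrac & mn > overallMean
    lab <- if (all(expresses[panel$neuron])) "neuronal"
    else if (expresses[panel$glia]) "glia"
    else if (expresses[panel$muscle]) "muscle"
    else if (expresses[panel$epithelium]) "epithelium"
    else if (expresses[panel$support]) "support"
    else "other_nonneuronal"
    clusterClass[as.character(k)] <- lab
  }
  cellClass <- clusterClass[as.character(cl)]
  list(clusterClass = clusterClass,
       cellClass = stats::setNames(unname(cellClass), colnames(ae)))
}

#' Default receptor-combination category rules
#'
#' Ordered first-match rules mapping the boolean receptor-class predicates
#' (any tuning Or called, orco, any tuning Ir, any irco, any Gr, Rh50,
#' nompC) to a category label. NA means "don't care"; the final catch-all
#' row makes the table exhaustive. The table is data, not code: it can be
#' edited, written to and read from TSV. The default ordering puts the
#' purely mechanosensory/ammonia categories first (they require the
#' absence of chemoreceptor calls), then non-Or chemosensory categories,
#' then the Or/orco combinations; a cell calling orco with tuning Ir and
#' irco lands in the orco+Ir+irco category whether or not a tuning Or is
#' also called.
#'
#' @return data.frame with columns \code{label}, \code{anyOr}, \code{orco},
#'   \code{anyIr}, \code{anyIrco}, \code{anyGr}, \code{Rh50}, \code{nompC}.
#' @export
defaultCategoryRules <- function() {
  r <- function(label, anyOr = NA, orco = NA, anyIr = NA, anyIrco = NA,
                anyGr = NA, Rh50 = NA, nompC = NA)
    data.frame(label = label, anyOr = anyOr, orco = orco, anyIr = anyIr,
               anyIrco = anyIrco, anyGr = anyGr, Rh50 = Rh50, nompC = nompC,
               stringsAsFactors = FALSE)
  rbind(
    r("mechanosensory", nompC = TRUE, anyOr = FALSE, orco = FALSE,
      anyIr = FALSE, anyIrco = FALSE, anyGr = FALSE),
    r("ammonia_Rh50", Rh50 = TRUE, anyOr = FALSE, orco = FALSE,
      anyIr = FALSE, anyIrco = FALSE, anyGr = FALSE, nompC = FALSE),
    r("Gr_only", anyGr = TRUE, anyOr = FALSE, orco = FALSE, anyIr = FALSE,
      anyIrco = FALSE),
    r("Ir_irco", anyIr = TRUE, anyIrco = TRUE, anyOr = FALSE, orco = FALSE,
      anyGr = FALSE),
    r("Gr_Ir_coreceptor", anyGr = TRUE, anyIrco = TRUE, anyOr = FALSE,
      orco = FALSE),
    r("Gr_Ir_coreceptor", anyGr = TRUE, anyIr = TRUE, anyOr = FALSE,
      orco = FALSE),
    r("Gr_Ir_coreceptor", anyIrco = TRUE, anyOr = FALSE, orco = FALSE,
      anyIr = FALSE, anyGr = FALSE),
    r("OrX_orco_Gr", anyOr = TRUE, orco = TRUE, anyGr = TRUE),
    r("OrX_orco_irco", anyOr = TRUE, orco = TRUE, anyIrco = TRUE,
      anyIr = FALSE),
    r("orco_Ir_irco", orco = TRUE, anyIr = TRUE, anyIrco = TRUE),
    r("OrX_orco", anyOr = TRUE, orco = TRUE),
    r("orco_only", orco = TRUE),
    r("neuron_unclassified"))
}

#' Assign a receptor-combination category to each cell
#'
#' Nonneuronal cells keep their gated cluster label. Neuronal cells are
#' evaluated against the ordered rule table on the seven receptor-class
#' predicates derived from their call row; the first matching rule wins.
#'
#' @param rc a \linkS4class{ReceptorCalls}.
#' @param cellClass per-cell class labels from \code{\link{gateClusters}}.
#' @param geneAnno gene annotation (for receptor classes of the call
#'   columns).
#' @param rules rule table, see \code{\link{defaultCategoryRules}}.
#' @return character vector of category labels, named by cell id.
#' @export
assignCategories <- function(rc, cellClass, geneAnno,
                             rules = defaultCategoryRules()) {
  cm <- calls(rc)
  cls <- stats::setNames(geneAnno$gene_class, geneAnno$gene_id)[colnames(cm)]
  pred <- cbind(
    anyOr = rowSums(cm[, cls == "tuning_Or", drop = FALSE]) > 0,
    orco = rowSums(cm[, cls == "orco", drop = FALSE]) > 0,
    anyIr = rowSums(cm[, cls == "tuning_Ir", drop = FALSE]) > 0,
    anyIrco = rowSums(cm[, cls == "irco", drop = FALSE]) > 0,
    anyGr = rowSums(cm[, cls == "Gr", drop = FALSE]) > 0,
    Rh50 = rowSums(cm[, cls == "Rh50", drop = FALSE]) > 0,
    nompC = rowSums(cm[, cls == "nompC", drop = FALSE]) > 0)
  predNames <- colnames(pred)
  out <- cellClass
  neuronal <- which(cellClass == "neuronal")
  ruleMat <- as.matrix(rules[, predNames])
  for (i in neuronal) {
    for (j in seq_len(nrow(rules))) {
      cond <- ruleMat[j, ]
      if (all(is.na(cond) | cond == pred[i, ])) {
        out[i] <- rules$label[j]
        break
      }
    }
  }
  out
}

#' Assign one cell (rule-table evaluation)
#'
#' Single-cell form of \code{\link{assignCategories}} for rule-table
#' inspection: takes a named logical predicate vector directly.
#'
#' @param predicates named logical vector with elements \code{anyOr},
#'   \code{orco}, \code{anyIr}, \code{anyIrco}, \code{anyGr}, \code{Rh50},
#'   \code{nompC}.
#' @param rules rule table.
#' @return the category label of the first matching rule.
#' @export
assignCategory <- function(predicates, rules = defaultCategoryRules()) {
  for (j in seq_len(nrow(rules))) {
    cond <- unlist(rules[j, -1])
    if (all(is.na(cond) | cond == predicates[names(cond)]))
      return(rules$label[j])
  }
  stop("rule table is not exhaustive") # unreachable with the default table
}

#' Wild-type versus mutant survival table
#'
#' Per-category cell counts and within-genotype fractions, a depletion
#' odds ratio (mutant odds of being in the category over wild-type odds,
#' with the Haldane-Anscombe 0.5 correction when any count is zero) and a
#' two-sided hypergeometric p-value on the 2x2 table. The odds-ratio test
#' is an extension beyond the reference analysis, which reports
#' proportions only; it is labelled as such in the output. Categories
#' empty in both genotypes are dropped with a log message. Also records
#' the overall neuron fraction per genotype.
#'
#' @param categories per-cell category labels.
#' @param genotypes per-cell genotype ("WT"/"mutant").
#' @return data.frame (one row per category) with attribute
#'   \code{neuron_fraction}.
#' @export
survivalTable <- function(categories, genotypes) {
  stopifnot(length(categories) == length(genotypes))
  cats <- if (is.factor(categories)) levels(categories)
          else sort(unique(categories))
  categories <- as.character(categories)
  nWT <- sum(genotypes == "WT")
  nMUT <- sum(genotypes == "mutant")
  rows <- lapply(cats, function(cat) {
    a <- sum(categories == cat & genotypes == "WT")
    b <- sum(categories == cat & genotypes == "mutant")
    if (a + b == 0) return(NULL)
    restWT <- nWT - a
    restMUT <- nMUT - b
    hal <- if (any(c(a, b, restWT, restMUT) == 0)) 0.5 else 0
    orr <- ((b + hal) / (restMUT + hal)) / ((a + hal) / (restWT + hal))
    p <- if (nWT > 0 && nMUT > 0)
      stats::fisher.test(matrix(c(a, restWT, b, restMUT), 2))$p.value
    else NA_real_
    data.frame(category = cat, n_WT = a, n_mutant = b,
               fraction_WT = if (nWT > 0) a / nWT else NA_real_,
               fraction_mutant = if (nMUT > 0) b / nMUT else NA_real_,
               depletion_odds_ratio = orr, p = p,
               stringsAsFactors = FALSE)
  })
  dropped <- cats[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    logMsg("categories empty in both genotypes dropped: ",
           paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  neuronCat <- setdiff(out$category, NONNEURONAL_LABELS)
  attr(out, "neuron_fraction") <- c(
    WT = if (nWT > 0)
      sum(out$n_WT[out$category %in% neuronCat]) / nWT else NA_real_,
    mutant = if (nMUT > 0)
      sum(out$n_mutant[out$category %in% neuronCat]) / nMUT else NA_real_)
  attr(out, "note") <- paste("depletion_odds_ratio and p are an extension;",
                             "the reference analysis reports proportions only")
  out
}
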