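#' Simulate a pair of tandem gene clusters for ID transfer
#'
#' Emulates the situations met when transferring tandem-cluster gene IDs
#' between two genome assemblies. List B is list A after per-gene sequence
#' divergence; a similarity table (bit score, percent identity, alignment
#' length) covers true pairs and tandem neighbors. Truncated genes keep
#' their percent identity but lose most of their alignment length, so a
#' paralogous neighbor outscores the true partner on bit score. Collapsed
#' genes are absent from list B entirely and instead hit a neighboring
#' region with near-partner identity (the erroneous-duplication /
#' assembly-collapse signature): the collapsed gene and its neighbor then
#' share the same best hit.
#'
#' @param nGenes genes in list A.
#' @param fracTruncated fraction of genes whose new-assembly model is
#'   truncated.
#' @param fracCollapsed fraction of genes collapsed away in the new
#'   assembly; \code{fracTruncated + fracCollapsed} must be < 1.
#' @param seed RNG seed.
#' @return a list with \code{listA}, \code{listB} (ordered id vectors),
#'   \code{similarity} (data.frame: query, subject, pct_identity,
#'   aln_length, bit_score) and \code{truth} (true partner per A gene, NA
#'   for collapsed, plus the truncated/collapsed id sets).
#' @export
simulateClusterPair <- function(nGenes = 100, fracTruncated = 0.1,
                                fracCollapsed = 0.05, seed = 1) {
  if (fracTruncated < 0 || fracCollapsed < 0 ||
      fracTruncated + fracCollapsed >= 1)
    stop("fractions must be nonnegative with fracTruncated + fracCollapsed < 1")
  aIds <- sprintf("oldOr%03d", seq_len(nGenes))
  bIds <- sprintf("LOC%05d", seq_len(nGenes))
  withSeed(stageSeed(seed, "simulate_pair"), {
    nT <- round(fracTruncated * nGenes)
    nC <- round(fracCollapsed * nGenes)
    pick <- sample(nGenes, nT + nC)
    truncated <- sort(pick[seq_len(nT)])
    collapsed <- sort(pick[nT + seq_len(nC)])
    # a collapsed gene collapses into an ordinary (present, untruncated)
    # neighbor, as in the assembly-collapse scenario
    nbOf <- function(i) {
      cand <- c(i - 1, i + 1, i - 2, i + 2)
      cand <- cand[cand >= 1 & cand <= nGenes & !(cand %in% collapsed) &
                     !(cand %in% truncated)]
      if (!length(cand)) NA_integer_ else cand[1]
    }
    trueId <- stats::runif(nGenes, 88, 99)
    trueLen <- round(stats::runif(nGenes, 900, 1800))
    bit <- function(len, id) round(2 * len * id / 100, 1)

    rows <- list()
    addRow <- function(q, s, id, len)
      data.frame(query = q, subject = s, pct_identity = round(id, 1),
                 aln_length = len, bit_score = bit(len, id),
                 stringsAsFactors = FALSE)
    for (i in seq_len(nGenes)) {
      if (!(i %in% collapsed)) {
        len <- if (i %in% truncated) round(0.25 * trueLen[i]) else trueLen[i]
        rows[[length(rows) + 1]] <- addRow(aIds[i], bIds[i], trueId[i], len)
      }
      # paralogous tandem neighbors
      for (j in c(i - 1, i + 1, i - 2, i + 2)) {
        if (j < 1 || j > nGenes || j %in% collapsed) next
        idnt <- if (abs(i - j) == 1) stats::runif(1, 62, 78)
                else stats::runif(1, 50, 62)
        rows[[length(rows) + 1]] <-
          addRow(aIds[i], bIds[j], idnt, round(stats::runif(1, 500, 1200)))
      }
    }
    for (i in collapsed) {
      j <- nbOf(i)
      if (is.na(j)) next
      # near-partner identity, but bit score kept below the neighbor's own
      idnt <- trueId[j] - stats::runif(1, 2, 6)
      len <- round(0.85 * trueLen[j])
      k <- which(vapply(rows, function(r)
        r$query == aIds[i] && r$subject == bIds[j], TRUE))
      rows[[k[1]]] <- addRow(aIds[i], bIds[j], idnt, len)
    }
    sim <- do.call(rbind, rows)
    truthPartner <- stats::setNames(bIds, aIds)
    truthPartner[aIds[collapsed]] <- NA_character_
    list(listA = aIds,
         listB = if (length(collapsed)) bIds[-collapsed] else bIds,
         similarity = sim,
         truth = list(partner = truthPartner,
                      truncated = aIds[truncated],
                      collapsed = aIds[collapsed]))
  })
}
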