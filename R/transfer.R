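#' Reciprocal best hits
#'
#' Pair (a, b) is matched iff b is a's unique top bit-score hit and a is
#' b's unique top bit-score hit; exact ties leave the gene unmatched at
#' this tier. Missing pairs count as score 0.
#'
#' @param similarity data.frame with \code{query}, \code{subject},
#'   \code{bit_score} (and \code{pct_identity}).
#' @return data.frame \code{gene_A}, \code{gene_B} of matched pairs
#'   (possibly empty).
#' @export
reciprocalBestHits <- function(similarity) {
  if (!nrow(similarity))
    return(data.frame(gene_A = character(), gene_B = character(),
                      stringsAsFactors = FALSE))
  topOf <- function(keys, vals, scores) {
    out <- lapply(split(seq_along(keys), keys), function(idx) {
      s <- scores[idx]
      best <- which(s == max(s))
      if (length(best) != 1) NA_character_ else vals[idx[best]]
    })
    unlist(out)
  }
  bestB <- topOf(similarity$query, similarity$subject, similarity$bit_score)
  bestA <- topOf(similarity$subject, similarity$query, similarity$bit_score)
  a <- names(bestB)
  matched <- !is.na(bestB) & !is.na(bestA[bestB]) & bestA[bestB] == a
  data.frame(gene_A = a[matched], gene_B = unname(bestB[matched]),
             stringsAsFactors = FALSE)
}

# order-preserving global alignment of two id vectors, score = similarity
# lookup (0 when the pair is absent), linear gap penalty; ties resolved
# match > gap-in-B > gap-in-A so the traceback is deterministic
alignInterval <- function(aGenes, bGenes, simScore, gapPenalty) {
  n <- length(aGenes); m <- length(bGenes)
  if (!n || !m) return(data.frame(gene_A = character(), gene_B = character(),
                                  score = numeric(), stringsAsFactors = FALSE))
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -gapPenalty * (0:n)
  S[1, ] <- -gapPenalty * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- simScore(aGenes[i], bGenes[j])
    S[i + 1, j + 1] <- max(S[i, j] + sc, S[i, j + 1] - gapPenalty,
                           S[i + 1, j] - gapPenalty)
  }
  pairs <- list()
  i <- n; j <- m
  while (i > 0 && j > 0) {
    sc <- simScore(aGenes[i], bGenes[j])
    if (S[i + 1, j + 1] == S[i, j] + sc) {
      pairs[[length(pairs) + 1]] <-
        data.frame(gene_A = aGenes[i], gene_B = bGenes[j], score = sc,
                   stringsAsFactors = FALSE)
      i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i + 1, j] - gapPenalty) {
      j <- j - 1
    } else {
      i <- i - 1
    }
  }
  do.call(rbind, rev(pairs))
}

#' Synteny-guided fill of the RBH matching
#'
#' Between consecutive reciprocal-best-hit anchor pairs, the unassigned A
#' and B genes are aligned by an order-preserving global alignment whose
#' pairwise score is the percent identity (not the bit score: a truncated
#' gene model shortens the alignment and deflates the score, but leaves
#' identity intact). Aligned pairs at or above \code{minIdentity} get
#' evidence \code{synteny_identity}. Unaligned A genes whose top bit-score
#' hit is shared with another A gene are flagged
#' \code{unmatched_collapsed} (the assembly-collapse signature); other
#' unaligned A genes are \code{unmatched_novel}. Anchors that cross in B
#' order are demoted to candidates with a warning and the fill recomputed.
#'
#' @param rbh matching from \code{\link{reciprocalBestHits}}.
#' @param listA,listB gene ids ordered by genomic position.
#' @param similarity similarity table (see
#'   \code{\link{readSimilarityTable}}).
#' @param gapPenalty alignment gap penalty in identity points (default 40).
#' @param minIdentity minimum percent identity for a synteny-tier
#'   assignment (default 60).
#' @return data.frame \code{gene_A}, \code{gene_B} (NA when unmatched),
#'   \code{evidence} in \{RBH, synteny_identity, unmatched_collapsed,
#'   unmatched_novel\}, \code{note}; one row per A gene, each B gene
#'   assigned at most once.
#' @export
syntenyFill <- function(rbh, listA, listB, similarity, gapPenalty = 40,
                        minIdentity = 60) {
  key <- paste(similarity$query, similarity$subject, sep = "\r")
  identLookup <- stats::setNames(similarity$pct_identity, key)
  simScore <- function(a, b) {
    v <- identLookup[paste(a, b, sep = "\r")]
    if (is.na(v)) 0 else unname(v)
  }
  rbh <- rbh[rbh$gene_A %in% listA & rbh$gene_B %in% listB, , drop = FALSE]
  rbh <- rbh[order(match(rbh$gene_A, listA)), , drop = FALSE]
  # demote anchors that cross in B order (longest increasing subsequence)
  bPos <- match(rbh$gene_B, listB)
  if (nrow(rbh) > 1) {
    keep <- longestIncreasing(bPos)
    if (length(keep) < nrow(rbh)) {
      warning("crossing RBH anchor(s) demoted to candidates: ",
              paste(rbh$gene_A[-keep], collapse = ", "))
      rbh <- rbh[keep, , drop = FALSE]
    }
  }
  # top bit-score hit per A gene (for collapse detection)
  topHit <- vapply(split(seq_len(nrow(similarity)), similarity$query),
                   function(idx) {
                     s <- similarity$bit_score[idx]
                     similarity$subject[idx[which.max(s)]]
                   }, "")
  assigned <- stats::setNames(rep(NA_character_, length(listA)), listA)
  evidence <- stats::setNames(rep(NA_character_, length(listA)), listA)
  note <- stats::setNames(rep("", length(listA)), listA)
  assigned[rbh$gene_A] <- rbh$gene_B
  evidence[rbh$gene_A] <- "RBH"

  aAnchor <- c(0L, match(rbh$gene_A, listA), length(listA) + 1L)
  bAnchor <- c(0L, match(rbh$gene_B, listB), length(listB) + 1L)
  for (seg in seq_len(length(aAnchor) - 1)) {
    aGap <- listA[seq_len(length(listA))[
      seq_along(listA) > aAnchor[seg] & seq_along(listA) < aAnchor[seg + 1]]]
    bGap <- listB[seq_len(length(listB))[
      seq_along(listB) > bAnchor[seg] & seq_along(listB) < bAnchor[seg + 1]]]
    if (!length(aGap)) next
    aln <- alignInterval(aGap, bGap, simScore, gapPenalty)
    if (nrow(aln)) {
      good <- aln$score >= minIdentity
      assigned[aln$gene_A[good]] <- aln$gene_B[good]
      evidence[aln$gene_A[good]] <- "synteny_identity"
      note[aln$gene_A[good]] <- sprintf("identity %.1f", aln$score[good])
    }
  }
  open <- is.na(assigned)
  for (a in listA[open]) {
    th <- topHit[a]
    shared <- !is.na(th) && th %in% topHit[setdiff(names(topHit), a)]
    evidence[a] <- if (isTRUE(shared)) "unmatched_collapsed"
                   else "unmatched_novel"
    note[a] <- if (isTRUE(shared))
      paste0("top hit ", th, " shared with another query") else
        "no syntenic partner"
  }
  data.frame(gene_A = listA, gene_B = unname(assigned[listA]),
             evidence = unname(evidence[listA]), note = unname(note[listA]),
             stringsAsFactors = FALSE)
}

longestIncreasing <- function(x) {
  n <- length(x)
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    if (x[j] < x[i] && best[j] + 1L > best[i]) {
      best[i] <- best[j] + 1L; prev[i] <- j
    }
  i <- which.max(best)
  out <- integer()
  while (i > 0) { out <- c(i, out); i <- prev[i] }
  out
}

#' Transfer report
#'
#' Evidence-tier counts and the collapsed/novel gene lists for an ID
#' transfer.
#'
#' @param assignments output of \code{\link{syntenyFill}}.
#' @return list with \code{tier_counts} (named integer vector),
#'   \code{collapsed}, \code{novel}, and the assignment table.
#' @export
transferReport <- function(assignments) {
  tiers <- c("RBH", "synteny_identity", "unmatched_collapsed",
             "unmatched_novel")
  cnt <- stats::setNames(integer(length(tiers)), tiers)
  if (nrow(assignments)) {
    tb <- table(assignments$evidence)
    cnt[names(tb)] <- as.integer(tb)
  }
  list(tier_counts = cnt,
       collapsed = assignments$gene_A[assignments$evidence ==
                                        "unmatched_collapsed"],
       novel = assignments$gene_A[assignments$evidence == "unmatched_novel"],
       assignments = assignments)
}
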