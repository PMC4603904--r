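## Read-pair merging: probabilistic overlap criterion and quality-based
## mismatch reconciliation.

#' Probability of an overlap's matches arising by chance
#'
#' Upper-tail binomial probability of observing at least
#' \code{nMatches} matching bases in an overlap of \code{overlapLen}
#' positions when bases match at random with probability
#' \code{nullMatchProb} (0.25 for i.i.d. uniform bases).
#'
#' @param overlapLen Overlap length in bp.
#' @param nMatches Observed number of matching positions.
#' @param nullMatchProb Null per-position match probability.
#' @return The chance probability; overlaps merge when the minimum over
#'   candidate overlaps falls below the merge threshold.
#' @examples
#' overlapProbability(30, 30)          # 0.25^30, far below 1e-10
#' overlapProbability(10, 10)          # ~9.5e-7, not significant
#' @export
overlapProbability <- function(overlapLen, nMatches, nullMatchProb = 0.25) {
  if (any(nMatches > overlapLen) || any(nMatches < 0)) {
    stop("overlapProbability(): need 0 <= nMatches <= overlapLen")
  }
  binomUpperTail(nMatches, overlapLen, nullMatchProb)
}

#' Parameters of the read-pair merger
#'
#' @param pThreshold Chance probability below which the best overlap is
#'   accepted (default 1e-10).
#' @param nullMatchProb Null per-position match probability (default
#'   0.25, i.i.d. uniform bases).
#' @param minOverlap Smallest overlap considered (default 5 bp; shorter
#'   overlaps cannot reach the threshold anyway).
#' @param qualCap Phred cap for combined qualities at agreeing overlap
#'   positions (default 60).
#' @return A list of merge parameters.
#' @export
mergeParams <- function(pThreshold = 1e-10, nullMatchProb = 0.25,
                        minOverlap = 5L, qualCap = 60L) {
  stopifnot(pThreshold > 0, pThreshold < 1,
            nullMatchProb > 0, nullMatchProb < 1)
  list(pThreshold = pThreshold, nullMatchProb = nullMatchProb,
       minOverlap = as.integer(minOverlap), qualCap = as.integer(qualCap))
}

#' Merge one read pair
#'
#' Evaluates every candidate overlap between read 1 and the
#' reverse-complemented mate (standard innie orientation), computes the
#' chance probability of each overlap's match count, and merges at the
#' overlap minimising that probability provided it falls below the
#' threshold. At agreeing overlap positions qualities are summed
#' (capped); at disagreements the higher-quality base is kept with the
#' quality difference. Pairs failing the criterion are returned
#' unmerged (they are kept separate but still used downstream).
#'
#' @param seq1,qual1 Read 1 sequence and Phred+33 quality string.
#' @param seq2,qual2 Read 2 sequence and quality string (as sequenced;
#'   reverse-complemented internally).
#' @param params A [mergeParams()] list.
#' @return A list: \code{merged} (logical); if merged, \code{seq},
#'   \code{qual}, \code{overlap}, \code{p}; otherwise the input pair.
#' @examples
#' p <- mergeParams()
#' a <- strrep("ACGT", 10)
#' mergePair(a, strrep("I", 40), revComp(a), strrep("I", 40), p)$overlap
#' @export
mergePair <- function(seq1, qual1, seq2, qual2, params = mergeParams()) {
  if (nchar(seq1) != nchar(qual1) || nchar(seq2) != nchar(qual2)) {
    stop("mergePair(): sequence and quality lengths differ")
  }
  if (!nchar(seq1) || !nchar(seq2)) stop("mergePair(): empty read")
  b <- revComp(seq2)
  bq <- revString(qual2)
  matches <- cpp_overlap_matches(seq1, b)
  overlaps <- seq_along(matches)
  keep <- overlaps >= params$minOverlap
  if (!any(keep)) {
    return(list(merged = FALSE, seq1 = seq1, qual1 = qual1,
                seq2 = seq2, qual2 = qual2))
  }
  pvals <- overlapProbability(overlaps[keep], matches[keep],
                              params$nullMatchProb)
  iBest <- which.min(pvals)
  pBest <- pvals[iBest]
  if (pBest >= params$pThreshold) {
    return(list(merged = FALSE, seq1 = seq1, qual1 = qual1,
                seq2 = seq2, qual2 = qual2, p = pBest))
  }
  o <- overlaps[keep][iBest]
  n1 <- nchar(seq1)
  n2 <- nchar(b)
  a1 <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  a2 <- strsplit(b, "", fixed = TRUE)[[1L]]
  q1 <- utf8ToInt(qual1) - 33L
  q2 <- utf8ToInt(bq) - 33L
  ovIdx1 <- (n1 - o + 1L):n1
  ovIdx2 <- seq_len(o)
  agree <- a1[ovIdx1] == a2[ovIdx2]
  hi1 <- q1[ovIdx1] >= q2[ovIdx2]
  outBase <- ifelse(agree, a1[ovIdx1],
                    ifelse(hi1, a1[ovIdx1], a2[ovIdx2]))
  outQ <- ifelse(agree, pmin(q1[ovIdx1] + q2[ovIdx2], params$qualCap),
                 abs(q1[ovIdx1] - q2[ovIdx2]))
  tail2 <- if (n2 > o) (o + 1L):n2 else integer(0L)
  mergedSeq <- paste(c(a1[seq_len(n1 - o)], outBase, a2[tail2]),
                     collapse = "")
  mergedQ <- intToUtf8(c(q1[seq_len(n1 - o)], outQ, q2[tail2]) + 33L)
  list(merged = TRUE, seq = mergedSeq, qual = mergedQ,
       overlap = o, p = pBest)
}

#' Merge a table of read pairs
#'
#' Driver over a read-pair table. Unmerged pairs are kept separate but
#' still used: both mates are emitted as independent assembly-ready
#' sequences.
#'
#' @param reads data.frame with columns \code{id, seq1, qual1, seq2,
#'   qual2}.
#' @param params A [mergeParams()] list.
#' @return A list: \code{merged} data.frame (\code{id, seq, qual,
#'   overlap, p}), \code{unmerged} data.frame of intact pairs,
#'   \code{fragments} data.frame with one row per assembly-ready
#'   sequence (merged reads, plus both mates of unmerged pairs mapped
#'   independently), and \code{stats} (pair count and merge rate).
#' @export
mergeReadPairs <- function(reads, params = mergeParams()) {
  n <- nrow(reads)
  isMerged <- logical(n)
  seqs <- character(n)
  quals <- character(n)
  overlaps <- integer(n)
  ps <- numeric(n)
  for (i in seq_len(n)) {
    r <- mergePair(reads$seq1[i], reads$qual1[i],
                   reads$seq2[i], reads$qual2[i], params)
    isMerged[i] <- r$merged
    if (r$merged) {
      seqs[i] <- r$seq
      quals[i] <- r$qual
      overlaps[i] <- r$overlap
      ps[i] <- r$p
    }
  }
  merged <- data.frame(id = reads$id[isMerged], seq = seqs[isMerged],
                       qual = quals[isMerged],
                       overlap = overlaps[isMerged], p = ps[isMerged],
                       stringsAsFactors = FALSE)
  unmerged <- data.frame(id = reads$id[!isMerged],
                         seq1 = reads$seq1[!isMerged],
                         qual1 = reads$qual1[!isMerged],
                         seq2 = reads$seq2[!isMerged],
                         qual2 = reads$qual2[!isMerged],
                         stringsAsFactors = FALSE)
  frags <- data.frame(
    id = c(merged$id, rep(unmerged$id, 2L)),
    mate = c(rep(0L, nrow(merged)), rep(1:2, each = nrow(unmerged))),
    seq = c(merged$seq, unmerged$seq1, unmerged$seq2),
    stringsAsFactors = FALSE
  )
  list(merged = merged, unmerged = unmerged, fragments = frags,
       stats = list(nPairs = n, nMerged = nrow(merged),
                    mergeRate = if (n) nrow(merged) / n else NA_real_))
}
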