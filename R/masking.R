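## Three-step conservation masking/trimming of per-locus alignments and
## alignment summary statistics.

alignmentToMatrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("alignment is ragged: rows have unequal lengths")
  }
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

matrixToAlignment <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Parameters of the three-step alignment masking
#'
#' @param goodFraction A site is good when its modal character (gaps
#'   count as a character, case ignored) occurs in strictly more than
#'   this fraction of the sequences (0.5).
#' @param windowLen Per-sequence window length in bases (20).
#' @param minGoodInWindow Windows with fewer good sites than this are
#'   masked in that sequence (10).
#' @param minUnmaskedPerColumn Columns with fewer unmasked bases than
#'   this are removed (4).
#' @param hardMask Write masked stretches as \code{N} instead of
#'   lowercase.
#' @return A list of masking parameters.
#' @export
maskParams <- function(goodFraction = 0.5, windowLen = 20L,
                       minGoodInWindow = 10L,
                       minUnmaskedPerColumn = 4L, hardMask = FALSE) {
  stopifnot(goodFraction > 0, goodFraction < 1,
            windowLen > 0, minGoodInWindow <= windowLen)
  list(goodFraction = goodFraction, windowLen = as.integer(windowLen),
       minGoodInWindow = as.integer(minGoodInWindow),
       minUnmaskedPerColumn = as.integer(minUnmaskedPerColumn),
       hardMask = isTRUE(hardMask))
}

## Step 1 of the masking: which columns of an alignment matrix are good?
goodSites <- function(m, goodFraction) {
  up <- toupper(m)
  apply(up, 2L, function(col) {
    max(table(col)) > goodFraction * length(col)
  })
}

#' Mask and trim an alignment in three conservation-based steps
#'
#' (1) A site is good when its most common character — gaps counted as
#' characters, case ignored — occurs in strictly more than 50 % of the
#' sequences. (2) For each sequence, every window of 20 consecutive
#' bases (its own residues, skipping its gaps) containing fewer than
#' 10 good sites is masked in that sequence; masked stretches become
#' lowercase (or \code{N} with \code{hardMask}). (3) Columns left with
#' fewer than 4 unmasked bases are removed from all rows. Because
#' column removal reshapes the windows, the three steps are iterated
#' to a fixed point. Lowercase residues in the input are treated as
#' already masked, so re-masking a soft-masked alignment is a no-op
#' (idempotent); hard masking with \code{N} discards the mask record.
#'
#' @param alignment Named character vector of equal-length rows, or a
#'   character matrix.
#' @param params A [maskParams()] list.
#' @return A list: \code{alignment} (masked, trimmed, named character
#'   vector), \code{annotations} (per original column: \code{good},
#'   \code{masked} or \code{removed}; a kept column is \code{masked}
#'   when any of its residues is masked), \code{keptColumns} (indices
#'   of surviving original columns), \code{iterations}.
#' @examples
#' al <- c(a = "ACGTACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGTACGT",
#'         c = "ACGTACGTACGTACGTACGTACGT", d = "ACGTACGTACGTACGTACGTACGT")
#' maskAlignment(al)$alignment
#' @export
maskAlignment <- function(alignment, params = maskParams()) {
  m <- alignmentToMatrix(alignment)
  if (!nrow(m) || !ncol(m)) stop("maskAlignment(): empty alignment")
  nOrig <- ncol(m)
  keptCols <- seq_len(nOrig)
  ## lowercase input residues are already soft-masked: keep them masked
  ## so that re-masking a soft-masked alignment is a no-op
  masked <- matrix(m %in% letters, nrow(m), ncol(m))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    good <- goodSites(m, params$goodFraction)
    ## step 2: per-sequence 20-base windows over the sequence's own
    ## residues
    newMask <- masked
    for (i in seq_len(nrow(m))) {
      resCols <- which(m[i, ] != "-")
      nres <- length(resCols)
      if (nres < params$windowLen) next
      gw <- good[resCols]
      cs <- cumsum(gw)
      w <- params$windowLen
      nGood <- cs[w:nres] - c(0, cs[seq_len(nres - w)])
      bad <- which(nGood < params$minGoodInWindow)
      for (b in bad) newMask[i, resCols[b:(b + w - 1L)]] <- TRUE
    }
    ## step 3: drop columns with too few unmasked bases
    unmaskedCount <- colSums(m != "-" & !newMask)
    drop <- unmaskedCount < params$minUnmaskedPerColumn
    changed <- any(newMask & !masked) || any(drop)
    masked <- newMask
    if (any(drop)) {
      m <- m[, !drop, drop = FALSE]
      masked <- masked[, !drop, drop = FALSE]
      keptCols <- keptCols[!drop]
    }
    if (!changed || !ncol(m)) break
  }
  out <- m
  if (ncol(out)) {
    out[masked & out != "-"] <-
      if (params$hardMask) "N" else tolower(out[masked & out != "-"])
    out[!masked] <- toupper(out[!masked])
  }
  ann <- rep("removed", nOrig)
  if (length(keptCols)) {
    colMasked <- colSums(masked & m != "-") > 0
    ann[keptCols] <- ifelse(colMasked, "masked", "good")
  }
  list(alignment = matrixToAlignment(out), annotations = ann,
       keptColumns = keptCols, iterations = iterations)
}

#' Alignment summary statistics
#'
#' Parsimony-informative (PI) sites are columns with at least two
#' distinct states (A, C, G or T; gaps and ambiguity codes are not
#' states) each present in at least two sequences. Uncorrected
#' divergence is the pairwise mismatch fraction over sites where both
#' sequences carry an unambiguous base. Case is ignored throughout.
#'
#' @param alignment Named character vector of equal-length rows, or a
#'   character matrix.
#' @return A list: \code{nSites}, \code{nSequences}, \code{piCount},
#'   \code{piFraction}, \code{divergence} (list with \code{mean},
#'   \code{min}, \code{max}; NA with fewer than two rows),
#'   \code{missingFraction} (gap or N cells). An empty alignment
#'   yields an empty summary (all zero/NA).
#' @export
summarizeAlignment <- function(alignment) {
  m <- toupper(alignmentToMatrix(alignment))
  n <- nrow(m)
  L <- ncol(m)
  if (!n || !L) {
    return(list(nSites = 0L, nSequences = n, piCount = 0L,
                piFraction = NA_real_,
                divergence = list(mean = NA_real_, min = NA_real_,
                                  max = NA_real_),
                missingFraction = NA_real_))
  }
  bases <- c("A", "C", "G", "T")
  pi <- apply(m, 2L, function(col) {
    tab <- table(col[col %in% bases])
    sum(tab >= 2L) >= 2L
  })
  div <- NULL
  if (n >= 2L) {
    pv <- c()
    ok <- matrix(m %in% bases, n, L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shared <- ok[i, ] & ok[j, ]
        pv <- c(pv, if (any(shared)) {
          mean(m[i, shared] != m[j, shared])
        } else NA_real_)
      }
    }
    pv <- pv[!is.na(pv)]
    div <- if (length(pv)) {
      list(mean = mean(pv), min = min(pv), max = max(pv))
    } else {
      list(mean = NA_real_, min = NA_real_, max = NA_real_)
    }
  } else {
    div <- list(mean = NA_real_, min = NA_real_, max = NA_real_)
  }
  list(nSites = L, nSequences = n, piCount = sum(pi),
       piFraction = sum(pi) / L, divergence = div,
       missingFraction = mean(m == "-" | m == "N"))
}
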