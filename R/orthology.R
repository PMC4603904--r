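## Orthology assessment: shared-20-mer distances and constrained
## neighbor-joining clustering of per-locus homolog sets.

## Tagged k-mer set of a sequence: consecutive 20-mers plus spaced
## 20-mers (every third base). The two kinds are tagged so a chance
## string collision between a consecutive and a spaced k-mer does not
## count as shared.
orthologKmerSet <- function(seq, k = 20L, spacing = 3L) {
  s <- toupper(seq)
  cons <- consecutiveKmers(s, k)
  cons <- cons[!grepl("[^ACGT]", cons)]
  sp <- spacedKmers(s, k, spacing)
  sp <- sp[!grepl("[^ACGT]", sp)]
  unique(c(if (length(cons)) paste0("c:", cons),
           if (length(sp)) paste0("s:", sp)))
}

#' Shared-20-mer distance between two consensus sequences
#'
#' One minus the shared fraction of the combined consecutive and
#' spaced (every third base) 20-mer sets of the two sequences.
#' Soft-masked (lowercase) content participates uppercased; k-mers
#' spanning non-ACGT characters are excluded.
#'
#' @param seqA,seqB Sequences (>= \code{k} bp).
#' @param k K-mer length (20).
#' @param spacing Spacing of the spaced k-mers (3).
#' @param normalization \code{"jaccard"} (default) divides the shared
#'   count by the union; \code{"min"} divides by the smaller set.
#' @return Distance in [0, 1]: 0 for identical sequences, 1 when no
#'   k-mer is shared.
#' @examples
#' kmerDistance(strrep("ACGT", 30), strrep("ACGT", 30))  # 0
#' @export
kmerDistance <- function(seqA, seqB, k = 20L, spacing = 3L,
                         normalization = c("jaccard", "min")) {
  normalization <- match.arg(normalization)
  if (nchar(seqA) < k || nchar(seqB) < k) {
    stop("kmerDistance(): sequences must be at least ", k, " bp")
  }
  ka <- orthologKmerSet(seqA, k, spacing)
  kb <- orthologKmerSet(seqB, k, spacing)
  if (!length(ka) || !length(kb)) {
    stop("kmerDistance(): a sequence yields no usable ", k, "-mers")
  }
  shared <- length(intersect(ka, kb))
  denom <- switch(normalization,
                  jaccard = length(union(ka, kb)),
                  min = min(length(ka), length(kb)))
  1 - shared / denom
}

#' Pairwise shared-20-mer distance matrix
#'
#' @param seqs Named character vector of sequences.
#' @param ... Passed to [kmerDistance()].
#' @return Symmetric matrix with zero diagonal.
#' @export
kmerDistanceMatrix <- function(seqs, ...) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  sets <- lapply(seqs, orthologKmerSet)
  short <- lengths(sets) == 0 | nchar(seqs) < 20L
  if (any(short)) {
    stop("kmerDistanceMatrix(): sequences too short for 20-mers: ",
         paste(names(seqs)[short], collapse = ", "))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <-
        1 - shared / length(union(sets[[i]], sets[[j]]))
    }
  }
  d
}

#' Constrained neighbor-joining clustering of a homolog set
#'
#' Agglomerates sequences by the neighbor-joining criterion
#' (smallest Q), with the constraint that a join is forbidden when the
#' merged cluster would contain two sequences from the same sample;
#' forbidden joins fall through to the next-best pair. Clustering
#' stops when every remaining pair is forbidden, and the remaining
#' nodes are the clusters (they partition the input).
#'
#' @param distMatrix Symmetric distance matrix (e.g. from
#'   [kmerDistanceMatrix()]).
#' @param samples Character vector: the sample of each row.
#' @param maxJoinDistance Joins between nodes farther apart than this
#'   are also forbidden (default \code{Inf}: sample constraint only).
#' @return List of integer vectors indexing \code{distMatrix} rows;
#'   each vector is one cluster with at most one member per sample.
#' @export
njClusterOrthologs <- function(distMatrix, samples,
                               maxJoinDistance = Inf) {
  n <- nrow(distMatrix)
  stopifnot(length(samples) == n, isSymmetric(unname(distMatrix)))
  members <- as.list(seq_len(n))
  nodeSamples <- as.list(samples)
  D <- distMatrix
  while (length(members) >= 2L) {
    m <- length(members)
    r <- rowSums(D)
    Q <- if (m > 2L) (m - 2) * D - outer(r, r, `+`) else D
    diag(Q) <- Inf
    ord <- order(Q[upper.tri(Q)])
    ut <- which(upper.tri(Q), arr.ind = TRUE)
    joined <- FALSE
    for (e in ord) {
      i <- ut[e, 1L]
      j <- ut[e, 2L]
      if (D[i, j] > maxJoinDistance) next
      if (length(intersect(nodeSamples[[i]], nodeSamples[[j]]))) next
      ## join i and j
      dnew <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)[-c(i, j)]
      members <- c(members[-c(i, j)],
                   list(c(members[[i]], members[[j]])))
      nodeSamples <- c(nodeSamples[-c(i, j)],
                       list(c(nodeSamples[[i]], nodeSamples[[j]])))
      D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE], dnew),
                 c(dnew, 0))
      joined <- TRUE
      break
    }
    if (!joined) break
  }
  members
}

#' Assess orthology of a consensus set
#'
#' Groups each locus's consensus sequences across samples into a
#' homolog set, clusters them by shared-20-mer distance under the
#' one-sequence-per-sample constraint, and retains clusters covering
#' at least \code{minSpeciesFraction} of the species (the 50 % rule;
#' the boundary is inclusive). The retained cluster with most members
#' becomes the locus's ortholog set.
#'
#' @param consensus A \code{ConsensusSet} (or a list with elements
#'   \code{table} and \code{sequences} shaped like its slots).
#' @param nSpecies Number of species in the study (denominator of the
#'   species fraction).
#' @param minSpeciesFraction Retention threshold (default 0.5,
#'   inclusive).
#' @return A list: \code{assignments} data.frame (\code{locus, cluster,
#'   sample, name, speciesFraction, retained, selected}), \code{sets}
#'   (named list: locus to named sample-to-sequence vector of the
#'   selected ortholog set), \code{summary} data.frame per locus.
#' @export
assessOrthology <- function(consensus, nSpecies,
                            minSpeciesFraction = 0.5) {
  if (methods::is(consensus, "ConsensusSet")) {
    tab <- consensusTable(consensus)
    seqs <- consensusSequences(consensus)
  } else {
    tab <- consensus$table
    seqs <- consensus$sequences
  }
  stopifnot(nSpecies >= 1)
  assignRows <- list()
  sets <- list()
  sumRows <- list()
  for (locus in unique(tab$locus)) {
    idx <- which(tab$locus == locus)
    lseqs <- seqs[idx]
    names(lseqs) <- paste(tab$sample[idx], tab$cluster[idx], sep = "|")
    samples <- tab$sample[idx]
    usable <- nchar(lseqs) >= 20L
    lseqs <- lseqs[usable]
    samples <- samples[usable]
    if (!length(lseqs)) next
    D <- kmerDistanceMatrix(lseqs)
    clusters <- njClusterOrthologs(D, samples)
    frac <- vapply(clusters,
                   function(g) length(unique(samples[g])) / nSpecies,
                   numeric(1L))
    retained <- frac >= minSpeciesFraction
    selected <- rep(FALSE, length(clusters))
    if (any(retained)) {
      cand <- which(retained)
      selected[cand[which.max(lengths(clusters)[cand])]] <- TRUE
    }
    for (ci in seq_along(clusters)) {
      g <- clusters[[ci]]
      assignRows[[paste(locus, ci)]] <- data.frame(
        locus = locus, cluster = ci, sample = samples[g],
        name = names(lseqs)[g], speciesFraction = frac[ci],
        retained = retained[ci], selected = selected[ci],
        stringsAsFactors = FALSE
      )
    }
    if (any(selected)) {
      g <- clusters[[which(selected)]]
      sets[[locus]] <- stats::setNames(unname(lseqs[g]), samples[g])
    }
    sumRows[[locus]] <- data.frame(
      locus = locus, nSequences = length(lseqs),
      nClusters = length(clusters), nRetained = sum(retained),
      setSize = if (any(selected)) length(clusters[[which(selected)]])
      else 0L,
      speciesFraction = if (any(selected)) frac[selected] else 0,
      stringsAsFactors = FALSE
    )
  }
  list(assignments = {
    a <- do.call(rbind, c(assignRows, list(NULL)))
    if (!is.null(a)) rownames(a) <- NULL
    a
  },
  sets = sets,
  summary = {
    s <- do.call(rbind, c(sumRows, list(NULL)))
    if (!is.null(s)) rownames(s) <- NULL
    s
  })
}
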