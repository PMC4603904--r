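## Reference-guided assembly: spaced 20-mer mapping, 60-mer de novo
## extension, 60-mer co-occurrence read clustering, per-read alignment
## refinement, and binomial-model IUPAC consensus calling.

#' Parameters of the assembly stage
#'
#' @param kmerLen Spaced-seed length (20).
#' @param spacing Spacing of seed positions (every third base, so a
#'   20-mer spans 58 bp).
#' @param prelimMinMatches Spaced positions that must match for a
#'   preliminary hit (17 of 20).
#' @param confirmMinMatches Matches required (strictly more than this)
#'   within the aligned confirmation window (55 of 100); shorter
#'   windows require the same proportion.
#' @param confirmWindow Confirmation window length (100 bp).
#' @param extensionKmer Exact-match k-mer length of the de novo
#'   extender (60).
#' @param clusterMinCooccurrence Number of reads in which a 60-mer pair
#'   must co-occur to be linked (2).
#' @param minClusterReads Clusters with fewer reads are removed (10).
#' @param consensusErrorProb Assumed per-base sequencing error of the
#'   binomial consensus model (0.1).
#' @param consensusAlpha Significance level of the polymorphism test
#'   (0.05).
#' @param softmaskMinCoverage Sites with coverage below this are
#'   soft-masked to lowercase (5).
#' @param multiClusterMode \code{"all"} (default) forwards every
#'   surviving cluster per (locus, sample) to orthology, which is what
#'   lets the orthology stage separate paralogous copies;
#'   \code{"largest"} forwards only the largest cluster.
#' @param refineMaxShift Largest position shift tried during alignment
#'   refinement.
#' @param refineMinMismatch Reads with fewer mismatches against the
#'   column consensus than this are left untouched by refinement
#'   (isolated errors cannot be improved by a shift or a single gap).
#' @param refineMaxPasses Refinement passes over the cluster.
#' @return A list of assembly parameters.
#' @export
assemblyParams <- function(kmerLen = 20L, spacing = 3L,
                           prelimMinMatches = 17L,
                           confirmMinMatches = 55L,
                           confirmWindow = 100L,
                           extensionKmer = 60L,
                           clusterMinCooccurrence = 2L,
                           minClusterReads = 10L,
                           consensusErrorProb = 0.1,
                           consensusAlpha = 0.05,
                           softmaskMinCoverage = 5L,
                           multiClusterMode = c("all", "largest"),
                           refineMaxShift = 3L,
                           refineMinMismatch = 5L,
                           refineMaxPasses = 3L) {
  stopifnot(kmerLen > 0, prelimMinMatches > 0, confirmMinMatches > 0,
            minClusterReads > 0, extensionKmer > 0,
            consensusErrorProb > 0, consensusErrorProb < 1,
            consensusAlpha > 0, consensusAlpha < 1)
  list(kmerLen = as.integer(kmerLen), spacing = as.integer(spacing),
       prelimMinMatches = as.integer(prelimMinMatches),
       confirmMinMatches = as.integer(confirmMinMatches),
       confirmWindow = as.integer(confirmWindow),
       extensionKmer = as.integer(extensionKmer),
       clusterMinCooccurrence = as.integer(clusterMinCooccurrence),
       minClusterReads = as.integer(minClusterReads),
       consensusErrorProb = consensusErrorProb,
       consensusAlpha = consensusAlpha,
       softmaskMinCoverage = as.integer(softmaskMinCoverage),
       multiClusterMode = match.arg(multiClusterMode),
       refineMaxShift = as.integer(refineMaxShift),
       refineMinMismatch = as.integer(refineMinMismatch),
       refineMaxPasses = as.integer(refineMaxPasses))
}

#' Build a spaced 20-mer index over probe-region references
#'
#' Enumerates, for every reference, the spaced k-mers (every
#' \code{spacing}-th base over a \code{(kmerLen-1)*spacing + 1} bp
#' window) at each admissible offset. K-mers spanning non-ACGT
#' characters are excluded. The returned object also carries the raw
#' references used by the mapper's confirmation stage.
#'
#' @param references Named character vector of reference sequences
#'   (names are locus ids; duplicates are an error).
#' @param params An [assemblyParams()] list.
#' @return A \code{SpacedKmerIndex} (list with \code{references},
#'   \code{pattern}, and a \code{kmers} data.frame of postings:
#'   \code{kmer, locus, offset} with 0-based offsets).
#' @export
buildSpacedIndex <- function(references, params = assemblyParams()) {
  if (!length(references)) stop("buildSpacedIndex(): no references")
  if (is.null(names(references)) || anyDuplicated(names(references))) {
    stop("buildSpacedIndex(): references need unique locus ids")
  }
  pattern <- seq(0L, by = params$spacing, length.out = params$kmerLen)
  rows <- lapply(seq_along(references), function(r) {
    km <- spacedKmers(toupper(references[r]), params$kmerLen,
                      params$spacing)
    if (!length(km)) return(NULL)
    keep <- !grepl("[^ACGT]", km)
    if (!any(keep)) return(NULL)
    data.frame(kmer = km[keep], locus = names(references)[r],
               offset = which(keep) - 1L, stringsAsFactors = FALSE)
  })
  out <- list(references = references, pattern = pattern,
              kmers = do.call(rbind, rows),
              k = params$kmerLen, spacing = params$spacing)
  class(out) <- "SpacedKmerIndex"
  out
}

#' @export
print.SpacedKmerIndex <- function(x, ...) {
  cat("SpacedKmerIndex:", length(x$references), "loci,",
      if (is.null(x$kmers)) 0L else nrow(x$kmers),
      "spaced", paste0(x$k, "-mer"), "postings (spacing",
      paste0(x$spacing, ")"), "\n")
  invisible(x)
}

#' Map reads to probe-region references
#'
#' Two-stage spaced-seed mapping: a preliminary hit requires at least
#' \code{prelimMinMatches} of the spaced positions to match a reference
#' seed; preliminary hits are confirmed by counting matches over up to
#' \code{confirmWindow} aligned bases against the reference, requiring
#' strictly more than the \code{confirmMinMatches / confirmWindow}
#' proportion. Both orientations are tried; reads are reported in
#' reference orientation. Reads whose best confirmed score ties across
#' loci are discarded as ambiguous.
#'
#' @param seqs Character vector of read sequences.
#' @param index A [buildSpacedIndex()] object.
#' @param params An [assemblyParams()] list.
#' @param ids Optional read ids.
#' @return data.frame: \code{id, seq} (reference orientation),
#'   \code{locus} (NA when unmapped), \code{pos} (0-based reference
#'   position of the read start, possibly negative), \code{score},
#'   \code{status} in \{mapped, unmapped, ambiguous\}.
#' @export
mapReads <- function(seqs, index, params = assemblyParams(), ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  refs <- as.character(index$references)
  prop <- params$confirmMinMatches / params$confirmWindow
  fwd <- cpp_map_reads(seqs, refs, index$pattern,
                       params$prelimMinMatches, prop,
                       params$confirmWindow)
  rcSeq <- revComp(seqs)
  rev <- cpp_map_reads(rcSeq, refs, index$pattern,
                       params$prelimMinMatches, prop,
                       params$confirmWindow)
  useRev <- rev$score > fwd$score
  locus <- ifelse(useRev, rev$locus, fwd$locus)
  pos <- ifelse(useRev, rev$pos, fwd$pos)
  score <- ifelse(useRev, rev$score, fwd$score)
  status <- ifelse(locus > 0, "mapped",
                   ifelse(locus < 0, "ambiguous", "unmapped"))
  data.frame(
    id = ids,
    seq = ifelse(useRev, rcSeq, seqs),
    locus = ifelse(locus > 0, names(index$references)[pmax(locus, 1L)],
                   NA_character_),
    pos = pos, score = score, status = status,
    stringsAsFactors = FALSE
  )
}

#' @rdname mapReads
#' @param seq A single read sequence.
#' @export
mapRead <- function(seq, index, params = assemblyParams()) {
  mapReads(seq, index, params)[1L, ]
}

#' Recruit unmapped reads through exact shared 60-mers
#'
#' Fixed-point de novo extension: any unmapped read (either orientation)
#' sharing an exact \code{extensionKmer}-mer with an already-mapped read
#' joins that read's locus, with its position inferred from the shared
#' k-mer's reference position. Passes repeat until a full pass adds no
#' reads.
#'
#' @param mapped data.frame \code{id, seq, locus, pos} of mapped reads
#'   (reference orientation).
#' @param unmapped data.frame \code{id, seq} of unmapped reads.
#' @param params An [assemblyParams()] list.
#' @return A list: \code{mapped} (input plus recruited reads, with a
#'   \code{recruited} flag), \code{unmapped} (still-unmapped reads),
#'   \code{passes} (number of passes run).
#' @export
extendAssembly <- function(mapped, unmapped, params = assemblyParams()) {
  k <- params$extensionKmer
  if (!nrow(mapped)) stop("extendAssembly(): need at least one mapped read")
  mapped$recruited <- rep(FALSE, nrow(mapped))

  kmerTable <- function(df) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      km <- consecutiveKmers(df$seq[i], k)
      if (!length(km)) return(NULL)
      data.frame(kmer = km, locus = df$locus[i],
                 kpos = df$pos[i] + seq_along(km) - 1L,
                 stringsAsFactors = FALSE)
    })
    tbl <- do.call(rbind, rows)
    if (is.null(tbl)) return(NULL)
    tbl[!duplicated(tbl$kmer), ]
  }

  tbl <- kmerTable(mapped)
  if (is.null(tbl)) {
    return(list(mapped = mapped, unmapped = unmapped, passes = 0L))
  }
  ## precompute both-orientation k-mers of each unmapped read
  pend <- unmapped
  pendKmers <- lapply(seq_len(nrow(pend)), function(i) {
    list(fwd = consecutiveKmers(pend$seq[i], k),
         rev = consecutiveKmers(revComp(pend$seq[i]), k))
  })
  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (!nrow(pend)) break
    newRows <- vector("list", nrow(pend))
    hitIdx <- logical(nrow(pend))
    for (i in seq_len(nrow(pend))) {
      for (orient in c("fwd", "rev")) {
        km <- pendKmers[[i]][[orient]]
        if (!length(km)) next
        m <- match(km, tbl$kmer)
        j <- which(!is.na(m))
        if (length(j)) {
          loci <- tbl$locus[m[j]]
          locus <- names(which.max(table(loci)))
          jj <- j[loci == locus][1L]
          newRows[[i]] <- data.frame(
            id = pend$id[i],
            seq = if (orient == "rev") revComp(pend$seq[i]) else
              pend$seq[i],
            locus = locus,
            pos = tbl$kpos[m[jj]] - (jj - 1L),
            recruited = TRUE, stringsAsFactors = FALSE
          )
          hitIdx[i] <- TRUE
          break
        }
      }
    }
    if (!any(hitIdx)) break
    added <- do.call(rbind, newRows[hitIdx])
    mapped <- rbind(mapped, added)
    addTbl <- kmerTable(added)
    if (!is.null(addTbl)) {
      addTbl <- addTbl[!addTbl$kmer %in% tbl$kmer, ]
      tbl <- rbind(tbl, addTbl)
    }
    pend <- pend[!hitIdx, , drop = FALSE]
    pendKmers <- pendKmers[!hitIdx]
  }
  list(mapped = mapped, unmapped = pend, passes = passes)
}

## Minimal union-find over 1..n with path halving.
ufNew <- function(n) seq_len(n)
ufFind <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

#' Partition a locus's reads into assembly clusters
#'
#' Links two reads when they share at least
#' \code{clusterMinCooccurrence} distinct 60-mers and takes connected
#' components of the resulting read graph (single linkage). Reads
#' sharing enough 60-mers with nobody form their own clusters. Given
#' sufficient coverage and no contamination or duplication, a
#' single-copy locus yields a single cluster; diverged paralogous
#' copies share no 60-mer and separate.
#'
#' @param locusReads data.frame \code{id, seq, pos} of one locus's reads
#'   (one sample), in reference orientation.
#' @param params An [assemblyParams()] list.
#' @return List of clusters, each a list with \code{reads} (data.frame
#'   \code{id, seq, pos, gapPos}) ordered by decreasing size.
#' @export
clusterReads <- function(locusReads, params = assemblyParams()) {
  n <- nrow(locusReads)
  if (!n) return(list())
  k <- params$extensionKmer
  kmerList <- lapply(locusReads$seq, consecutiveKmers, k = k)
  allk <- unlist(kmerList, use.names = FALSE)
  if (!length(allk)) {
    ## reads shorter than the k-mer: every read its own cluster
    return(lapply(seq_len(n), function(i) {
      list(reads = data.frame(id = locusReads$id[i],
                              seq = locusReads$seq[i],
                              pos = locusReads$pos[i], gapPos = NA_integer_,
                              stringsAsFactors = FALSE))
    }))
  }
  uk <- unique(allk)
  ids <- lapply(kmerList, function(km) unique(match(km, uk)))
  nread <- lengths(ids)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), nread),
    j = unlist(ids), x = 1,
    dims = c(n, length(uk))
  )
  ## S[i, j] = number of distinct 60-mers shared by reads i and j
  S <- Matrix::tcrossprod(M)
  S <- methods::as(S, "TsparseMatrix")
  pi_ <- S@i + 1L
  pj <- S@j + 1L
  keep <- pi_ < pj & S@x >= params$clusterMinCooccurrence
  uf <- ufNew(n)
  for (e in which(keep)) {
    r0 <- ufFind(uf, pi_[e])
    r1 <- ufFind(uf, pj[e])
    if (r1 != r0) uf[r1] <- r0
  }
  readComp <- vapply(seq_len(n), function(i) ufFind(uf, i), integer(1L))
  groups <- split(seq_len(n), readComp)
  groups <- groups[order(-lengths(groups))]
  lapply(groups, function(g) {
    list(reads = data.frame(id = locusReads$id[g], seq = locusReads$seq[g],
                            pos = locusReads$pos[g],
                            gapPos = NA_integer_,
                            stringsAsFactors = FALSE))
  })
}

## Character matrix of a cluster's reads, gaps applied, NA outside reads.
clusterMatrix <- function(reads) {
  off <- reads$pos - min(reads$pos)
  lens <- nchar(reads$seq) + !is.na(reads$gapPos)
  span <- max(off + lens)
  m <- matrix(NA_character_, nrow(reads), span)
  for (i in seq_len(nrow(reads))) {
    ch <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
    if (!is.na(reads$gapPos[i])) {
      ch <- append(ch, "-", after = reads$gapPos[i])
    }
    m[i, (off[i] + 1L):(off[i] + length(ch))] <- ch
  }
  m
}

## Per-column base counts (A,C,G,T rows) of a cluster matrix.
columnCounts <- function(m) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, 4L, ncol(m), dimnames = list(bases, NULL))
  for (b in seq_along(bases)) {
    out[b, ] <- colSums(m == bases[b], na.rm = TRUE)
  }
  out
}

## Total column agreement: sum over columns of the modal base count.
clusterAgreement <- function(reads) {
  cc <- columnCounts(clusterMatrix(reads))
  sum(apply(cc, 2L, max))
}

#' Refine read positions within an assembly cluster
#'
#' Re-aligns reads whose mismatch count against the column consensus is
#' large enough that a position shift or a single inserted gap could
#' help: each such read is tried at shifts up to
#' \code{refineMaxShift} and with one gap at each current mismatch
#' position, and the move maximising agreement with the other reads'
#' column consensus is kept only if the cluster's total column
#' agreement strictly increases. Total agreement therefore never
#' decreases, and perfectly agreeing clusters are fixed points.
#'
#' @param cluster A cluster from [clusterReads()].
#' @param params An [assemblyParams()] list.
#' @return The cluster with updated read positions/gaps.
#' @export
refineAlignment <- function(cluster, params = assemblyParams()) {
  reads <- cluster$reads
  if (is.null(reads$gapPos)) reads$gapPos <- NA_integer_
  n <- nrow(reads)
  if (n < 2L) {
    cluster$reads <- reads
    return(cluster)
  }
  maxShift <- params$refineMaxShift
  bases <- c("A", "C", "G", "T")
  for (pass in seq_len(params$refineMaxPasses)) {
    changed <- FALSE
    total <- clusterAgreement(reads)
    ## column counts of the whole cluster, computed once per pass;
    ## subtracting one read's own contribution gives the consensus of
    ## the other reads over the same coordinate frame
    obase <- min(reads$pos)
    Mfull <- clusterMatrix(reads)
    ccFull <- columnCounts(Mfull)
    for (i in seq_len(n)) {
      cc <- ccFull - columnCounts(Mfull[i, , drop = FALSE])
      modal <- bases[max.col(t(cc), ties.method = "first")]
      modal[colSums(cc) == 0] <- NA_character_

      scoreAt <- function(pos, gapPos) {
        ch <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
        if (!is.na(gapPos)) ch <- append(ch, "-", after = gapPos)
        idx <- (pos - obase) + seq_along(ch)
        ok <- idx >= 1L & idx <= length(modal)
        sum(ch[ok] == modal[idx[ok]], na.rm = TRUE)
      }

      cur <- scoreAt(reads$pos[i], reads$gapPos[i])
      len <- nchar(reads$seq[i])
      mismatches <- len - cur
      if (mismatches < params$refineMinMismatch) next

      cand <- expand.grid(shift = (-maxShift):maxShift,
                          gap = NA_integer_)
      ## one gap at each currently mismatching read position
      ch <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
      idx <- (reads$pos[i] - obase) + seq_along(ch)
      ok <- idx >= 1L & idx <= length(modal)
      mis <- which(ok & (is.na(modal[pmax(idx, 1L)]) |
                           ch != modal[pmax(idx, 1L)]))
      if (length(mis)) {
        cand <- rbind(cand, expand.grid(shift = (-maxShift):maxShift,
                                        gap = mis))
      }
      sc <- mapply(function(s, g) scoreAt(reads$pos[i] + s, g),
                   cand$shift, cand$gap)
      bi <- which.max(sc)
      if (sc[bi] > cur) {
        old <- reads[i, ]
        reads$pos[i] <- reads$pos[i] + cand$shift[bi]
        reads$gapPos[i] <- cand$gap[bi]
        newTotal <- clusterAgreement(reads)
        if (newTotal > total) {
          total <- newTotal
          changed <- TRUE
          ## positions moved: refresh the cached cluster counts
          obase <- min(reads$pos)
          Mfull <- clusterMatrix(reads)
          ccFull <- columnCounts(Mfull)
        } else {
          reads[i, ] <- old
        }
      }
    }
    if (!changed) break
  }
  cluster$reads <- reads
  cluster
}

#' Call an IUPAC consensus from an assembly cluster
#'
#' For each column with coverage n and e copies of non-majority bases,
#' the majority base is called when the polymorphism is explicable as
#' sequencing error, i.e. when P(X >= e) >= alpha for
#' X ~ Binomial(n, errorProb); otherwise the IUPAC code of all observed
#' bases is called (e.g. R for A+G). Ties for the majority base are
#' broken alphabetically. Sites with coverage below
#' \code{softmaskMinCoverage} are soft-masked to lowercase; covered-by-
#' nothing columns become gaps.
#'
#' @param cluster A cluster from [clusterReads()] (ideally refined).
#' @param params An [assemblyParams()] list.
#' @return A list: \code{sequence} (IUPAC string, lowercase where
#'   soft-masked), \code{coverage} (per-site), \code{nReads},
#'   \code{start} (0-based reference position of the first column).
#' @export
callConsensus <- function(cluster, params = assemblyParams()) {
  reads <- cluster$reads
  if (!nrow(reads)) stop("callConsensus(): empty cluster")
  m <- clusterMatrix(reads)
  cc <- columnCounts(m)
  cov <- colSums(cc)
  bases <- c("A", "C", "G", "T")
  majIdx <- apply(cc, 2L, which.max)           # alphabetical tie-break
  majCount <- cc[cbind(majIdx, seq_len(ncol(cc)))]
  e <- cov - majCount
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (cov[j] == 0) {
      out[j] <- "-"
      next
    }
    tailP <- binomUpperTail(e[j], cov[j], params$consensusErrorProb)
    call <- if (e[j] == 0L || tailP >= params$consensusAlpha) {
      bases[majIdx[j]]
    } else {
      iupacCode(bases[cc[, j] > 0])
    }
    if (cov[j] < params$softmaskMinCoverage) call <- tolower(call)
    out[j] <- call
  }
  list(sequence = paste(out, collapse = ""), coverage = cov,
       nReads = nrow(reads), start = min(reads$pos))
}

#' Drop low-coverage assembly clusters
#'
#' Removes clusters with fewer than \code{minClusterReads} reads —
#' the low-level contaminant filter.
#'
#' @param clusters List of clusters from [clusterReads()].
#' @param params An [assemblyParams()] list.
#' @return The surviving clusters.
#' @export
filterClusters <- function(clusters, params = assemblyParams()) {
  Filter(function(cl) nrow(cl$reads) >= params$minClusterReads, clusters)
}

#' Assemble one sample's reads
#'
#' Maps the sample's assembly-ready sequences (merged reads and both
#' mates of unmerged pairs) to the references, runs the de novo
#' extension to a fixed point, and per locus clusters, refines, filters
#' and consensus-calls the mapped reads.
#'
#' @param fragments data.frame \code{id, seq} of assembly-ready
#'   sequences (see [mergeReadPairs()]).
#' @param index A [buildSpacedIndex()] object.
#' @param params An [assemblyParams()] list.
#' @param sample Sample id used in the output tables.
#' @return A list: \code{consensus} data.frame (\code{locus, sample,
#'   cluster, nReads, length, meanCoverage, primary, sequence, start}),
#'   \code{clusterReport} data.frame (\code{locus, sample, nClusters,
#'   readsPerCluster, nFiltered}).
#' @export
assembleSample <- function(fragments, index, params = assemblyParams(),
                           sample = "sample") {
  mp <- mapReads(fragments$seq, index, params, ids = fragments$id)
  mapped <- mp[mp$status == "mapped",
               c("id", "seq", "locus", "pos")]
  unmapped <- mp[mp$status == "unmapped", c("id", "seq")]
  if (nrow(mapped)) {
    ext <- extendAssembly(mapped, unmapped, params)
    mapped <- ext$mapped
  }
  consRows <- list()
  repRows <- list()
  for (locus in unique(mapped$locus)) {
    lr <- mapped[mapped$locus == locus, c("id", "seq", "pos")]
    clusters <- clusterReads(lr, params)
    kept <- filterClusters(clusters, params)
    repRows[[locus]] <- data.frame(
      locus = locus, sample = sample, nClusters = length(clusters),
      readsPerCluster = paste(vapply(clusters,
                                     function(cl) nrow(cl$reads),
                                     integer(1L)), collapse = ","),
      nFiltered = length(clusters) - length(kept),
      stringsAsFactors = FALSE
    )
    if (!length(kept)) next
    if (params$multiClusterMode == "largest") kept <- kept[1L]
    for (ci in seq_along(kept)) {
      cl <- refineAlignment(kept[[ci]], params)
      cons <- callConsensus(cl, params)
      consRows[[paste(locus, ci)]] <- data.frame(
        locus = locus, sample = sample, cluster = ci,
        nReads = cons$nReads, length = nchar(cons$sequence),
        meanCoverage = mean(cons$coverage), primary = ci == 1L,
        sequence = cons$sequence, start = cons$start,
        stringsAsFactors = FALSE
      )
    }
  }
  list(consensus = do.call(rbind, c(consRows, list(NULL))),
       clusterReport = do.call(rbind, c(repRows, list(NULL))))
}

#' Run merging and assembly over a simulated dataset
#'
#' Convenience driver: for each sample, merges its read pairs, then
#' assembles against the dataset's per-locus references.
#'
#' @param dataset An \code{AnchoredDataset}.
#' @param params An [assemblyParams()] list.
#' @param mergeP A [mergeParams()] list.
#' @return A \code{ConsensusSet}.
#' @export
runAssembly <- function(dataset, params = assemblyParams(),
                        mergeP = mergeParams()) {
  index <- buildSpacedIndex(lociReferences(dataset), params)
  rd <- readPairs(dataset)
  consRows <- list()
  repRows <- list()
  for (s in unique(rd$sample)) {
    mg <- mergeReadPairs(rd[rd$sample == s, ], mergeP)
    asm <- assembleSample(mg$fragments, index, params, sample = s)
    consRows[[s]] <- asm$consensus
    repRows[[s]] <- asm$clusterReport
  }
  tab <- do.call(rbind, c(consRows, list(NULL)))
  if (is.null(tab)) {
    tab <- data.frame(locus = character(0), sample = character(0),
                      cluster = integer(0), nReads = integer(0),
                      length = integer(0), meanCoverage = numeric(0),
                      primary = logical(0), sequence = character(0),
                      start = integer(0))
  }
  rownames(tab) <- NULL
  new("ConsensusSet",
      table = tab[, setdiff(names(tab), "sequence")],
      sequences = tab$sequence,
      clusterReport = {
        cr <- do.call(rbind, c(repRows, list(NULL)))
        if (is.null(cr)) {
          cr <- data.frame(locus = character(0), sample = character(0),
                           nClusters = integer(0),
                           readsPerCluster = character(0),
                           nFiltered = integer(0))
        }
        rownames(cr) <- NULL
        cr
      })
}
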