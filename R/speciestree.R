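## Summary-statistic species-tree estimation: STAR (average ranks of
## coalescence events) and a triplet pseudo-likelihood search in the
## style of MP-EST.

## Coalescence ranks of a gene tree's internal nodes: the root of a
## tree with n taxa has rank n - 1 and each internal node has rank one
## less than its parent. Returns a full |taxa| x |taxa| matrix of the
## rank of each tip pair's MRCA (NA where a taxon is absent).
starRankMatrix <- function(tree, taxa) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  rank <- rep(NA_real_, nt + tree$Nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  rank[root] <- nt - 1
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    if (E[e, 2L] > nt) rank[E[e, 2L]] <- rank[E[e, 1L]] - 1
  }
  mr <- ape::mrca(tree)
  M <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  idx <- match(tree$tip.label, taxa)
  M[idx, idx] <- matrix(rank[mr], nt, nt)
  diag(M) <- NA_real_
  M
}

#' STAR pairwise distance matrix from gene trees
#'
#' For each gene tree, the root gets coalescence rank n - 1 (n = taxa
#' in that tree) and every internal node gets one less than its
#' parent; the distance between two taxa is twice the mean, over the
#' gene trees containing both, of the rank of their MRCA.
#'
#' @param geneTrees \code{multiPhylo} or list of rooted trees.
#' @param taxa Taxa of the matrix (default: union of tip labels).
#' @return Symmetric distance matrix (zero diagonal).
#' @export
starDistanceMatrix <- function(geneTrees, taxa = NULL) {
  if (!length(geneTrees)) stop("starDistanceMatrix(): no gene trees")
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(geneTrees, `[[`, "tip.label"))))
  }
  acc <- matrix(0, length(taxa), length(taxa))
  cnt <- matrix(0L, length(taxa), length(taxa))
  for (tr in geneTrees) {
    M <- starRankMatrix(tr, taxa)
    ok <- !is.na(M)
    acc[ok] <- acc[ok] + M[ok]
    cnt <- cnt + ok
  }
  offdiag <- row(cnt) != col(cnt)
  if (any(cnt[offdiag] == 0L)) {
    bad <- which(cnt == 0L & offdiag, arr.ind = TRUE)[1L, ]
    stop("starDistanceMatrix(): taxa ", taxa[bad[1L]], " and ",
         taxa[bad[2L]], " share no gene tree; distance undefined")
  }
  D <- 2 * acc / pmax(cnt, 1L)
  diag(D) <- 0
  dimnames(D) <- list(taxa, taxa)
  D
}

#' STAR species tree
#'
#' Neighbor-joining on the [starDistanceMatrix()] of the gene trees,
#' re-rooted by the outgroup when one is given. Without an outgroup
#' the tree is midpoint-rooted: rank distances are ultrametric in
#' expectation, so the midpoint coincides with the true root.
#'
#' @param geneTrees \code{multiPhylo} or list of rooted gene trees.
#' @param outgroup Optional outgroup label(s).
#' @param taxa Taxa to include (default: all observed).
#' @return A rooted \code{phylo} species tree.
#' @export
starTree <- function(geneTrees, outgroup = NULL, taxa = NULL) {
  D <- starDistanceMatrix(geneTrees, taxa)
  njRoot(ape::nj(as.dist(D)), outgroup)
}

## Root an NJ tree by outgroup when given, else by midpoint.
njRoot <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    og <- intersect(outgroup, tree$tip.label)
    if (length(og)) {
      return(ape::root(tree, outgroup = og, resolve.root = TRUE))
    }
  }
  phangorn::midpoint(tree)
}

## Topological (edge-count) depth of every node from the root.
nodeTopoDepth <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  depth <- rep(NA_real_, nt + tree$Nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  depth[root] <- 0
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    depth[E[e, 2L]] <- depth[E[e, 1L]] + 1
  }
  depth
}

## Branch-length depth of every node from the root.
nodeMetricDepth <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  depth <- rep(NA_real_, nt + tree$Nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  depth[root] <- 0
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    depth[E[e, 2L]] <- depth[E[e, 1L]] + tree$edge.length[e]
  }
  depth
}

## Full taxa x taxa matrix of MRCA depths (NA for absent taxa).
mrcaDepthMatrix <- function(tree, taxa, metric = FALSE) {
  nt <- length(tree$tip.label)
  depth <- if (metric) nodeMetricDepth(tree) else nodeTopoDepth(tree)
  mr <- ape::mrca(tree)
  M <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  idx <- match(tree$tip.label, taxa)
  M[idx, idx] <- matrix(depth[mr], nt, nt)
  M
}

## For each triple (rows of tripleIdx: i < j < k as indices into taxa)
## return which pair is the cherry in `tree`: 1 = {i,j}, 2 = {i,k},
## 3 = {j,k}, 0 = unresolved or taxon absent.
treeTripletCategories <- function(tree, taxa, tripleIdx) {
  M <- mrcaDepthMatrix(tree, taxa)
  d12 <- M[tripleIdx[, c(1L, 2L), drop = FALSE]]
  d13 <- M[tripleIdx[, c(1L, 3L), drop = FALSE]]
  d23 <- M[tripleIdx[, c(2L, 3L), drop = FALSE]]
  cat <- integer(nrow(tripleIdx))
  cat[d12 > d13 & d12 > d23] <- 1L
  cat[d13 > d12 & d13 > d23] <- 2L
  cat[d23 > d12 & d23 > d13] <- 3L
  cat[is.na(d12) | is.na(d13) | is.na(d23)] <- 0L
  cat
}

#' Rooted triplet counts over a set of gene trees
#'
#' For every species triple \{a, b, c\} (a < b < c), tallies how many
#' gene trees resolve it as ab|c, ac|b and bc|a. Trees missing a taxon
#' of a triple, or leaving it unresolved, do not contribute to that
#' triple.
#'
#' @param geneTrees \code{multiPhylo} or list of rooted gene trees.
#' @param taxa Taxa to enumerate (default: union of tip labels).
#' @return A list: \code{taxa}, \code{tripleIdx} (T x 3 index matrix
#'   into \code{taxa}), \code{counts} (T x 3: columns ab|c, ac|b,
#'   bc|a), \code{n} (row sums), \code{categories} (T x nTrees matrix
#'   of per-tree categories, 0 = no contribution).
#' @export
tripletCounts <- function(geneTrees, taxa = NULL) {
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(geneTrees, `[[`, "tip.label"))))
  }
  if (length(taxa) < 3L) stop("tripletCounts(): need at least 3 taxa")
  tripleIdx <- t(utils::combn(length(taxa), 3L))
  cats <- vapply(geneTrees, treeTripletCategories, taxa = taxa,
                 tripleIdx = tripleIdx,
                 FUN.VALUE = integer(nrow(tripleIdx)))
  cats <- matrix(cats, nrow = nrow(tripleIdx))
  counts <- t(apply(cats, 1L, tabulate, nbins = 3L))
  list(taxa = taxa, tripleIdx = tripleIdx, counts = counts,
       n = rowSums(counts), categories = cats)
}

## Triplet counts restricted to a subset of gene trees, reusing the
## per-tree category matrix.
subsetTripletCounts <- function(counts, treeIdx) {
  cats <- counts$categories[, treeIdx, drop = FALSE]
  sub <- t(apply(cats, 1L, tabulate, nbins = 3L))
  list(taxa = counts$taxa, tripleIdx = counts$tripleIdx, counts = sub,
       n = rowSums(sub), categories = cats)
}

#' Closed-form MP-EST branch-length estimate for one species triple
#'
#' The maximizer of the trinomial triplet likelihood given the matching
#' fraction p1 is t = -ln(1.5 (1 - p1)), clamped to
#' [\code{tMin}, \code{tMax}].
#'
#' @param pMatch Fraction of gene trees matching the species-tree
#'   triplet.
#' @param tMin,tMax Clamp bounds (coalescent units).
#' @return Branch length in coalescent units.
#' @examples
#' mpestBranchMLE(0.9)   # -log(1.5 * 0.1) = 1.897...
#' @export
mpestBranchMLE <- function(pMatch, tMin = 1e-6, tMax = 10) {
  stopifnot(pMatch >= 0, pMatch <= 1)
  t <- ifelse(pMatch >= 1, Inf, -log(1.5 * (1 - pMatch)))
  pmin(pmax(t, tMin), tMax)
}

#' MP-EST log pseudo-likelihood of a species tree
#'
#' Under the multispecies coalescent, a species triple whose internal
#' branch has length t (coalescent units) yields the matching gene
#' triplet with probability 1 - (2/3) exp(-t) and each alternative
#' with probability (1/3) exp(-t). The score is the sum over triples
#' of the multinomial log-likelihood of the observed triplet counts
#' (per-gene product; no multinomial coefficient).
#'
#' @param tree Rooted species tree with branch lengths in coalescent
#'   units (all >= 0).
#' @param counts A [tripletCounts()] object.
#' @return Log pseudo-likelihood.
#' @export
mpestScore <- function(tree, counts) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("mpestScore(): tree needs non-negative branch lengths")
  }
  taxa <- counts$taxa
  cat <- treeTripletCategories(tree, taxa, counts$tripleIdx)
  Mm <- mrcaDepthMatrix(tree, taxa, metric = TRUE)
  d12 <- Mm[counts$tripleIdx[, c(1L, 2L), drop = FALSE]]
  d13 <- Mm[counts$tripleIdx[, c(1L, 3L), drop = FALSE]]
  d23 <- Mm[counts$tripleIdx[, c(2L, 3L), drop = FALSE]]
  ## internal branch = cherry MRCA depth minus triple-root depth;
  ## the triple root is the shallowest of the three pairwise MRCAs
  cherry <- pmax(d12, d13, d23)
  outer <- pmin(d12, d13, d23)
  t <- pmax(cherry - outer, 0)
  t[cat == 0L] <- 0
  pm <- 1 - (2 / 3) * exp(-t)
  pa <- (1 / 3) * exp(-t)
  ll <- 0
  use <- counts$n > 0
  for (i in which(use)) {
    nm <- if (cat[i] >= 1L) counts$counts[i, cat[i]] else 0
    if (cat[i] == 0L) {
      ll <- ll + counts$n[i] * log(1 / 3)
    } else {
      na_ <- counts$n[i] - nm
      ll <- ll + nm * log(pm[i]) + na_ * log(pa[i])
    }
  }
  ll
}

## Profile log pseudo-likelihood of a topology: each triple's branch
## length is set to its closed-form MLE.
mpestProfileScore <- function(tree, counts, tMin = 1e-6, tMax = 10) {
  cat <- treeTripletCategories(tree, counts$taxa, counts$tripleIdx)
  use <- which(counts$n > 0)
  if (!length(use)) return(0)
  n <- counts$n[use]
  ci <- cat[use]
  nm <- ifelse(ci >= 1L,
               counts$counts[cbind(use, pmax(ci, 1L))], 0)
  that <- mpestBranchMLE(nm / n, tMin, tMax)
  pm <- 1 - (2 / 3) * exp(-that)
  pa <- (1 / 3) * exp(-that)
  sc <- ifelse(ci == 0L, n * log(1 / 3),
               nm * log(pm) + (n - nm) * log(pa))
  sum(sc)
}

## All rooted NNI neighbors of a rooted binary tree (topology only).
rootedNNINeighbors <- function(tree) {
  nt <- length(tree$tip.label)
  tree$edge.length <- NULL
  E <- tree$edge
  internal <- which(E[, 2L] > nt)
  out <- list()
  for (e in internal) {
    p <- E[e, 1L]
    ch <- E[e, 2L]
    sib <- E[E[, 1L] == p & E[, 2L] != ch, 2L]
    if (length(sib) != 1L) next
    kids <- which(E[, 1L] == ch)
    es <- which(E[, 1L] == p & E[, 2L] == sib)
    for (kx in kids) {
      t2 <- tree
      t2$edge[kx, 1L] <- p
      t2$edge[es, 1L] <- ch
      attr(t2, "order") <- NULL  # force a true cladewise reorder
      t2 <- stats::reorder(t2, "cladewise")
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

## Random rooted binary topology over taxa.
randomRootedTopology <- function(taxa) {
  tr <- ape::rtree(length(taxa), rooted = TRUE,
                   tip.label = sample(taxa))
  tr$edge.length <- NULL
  tr
}

#' MP-EST-style species-tree search
#'
#' Maximizes the triplet log pseudo-likelihood over rooted topologies
#' by nearest-neighbor-interchange hill-climbing, with each triple's
#' internal branch length profiled out by its closed-form MLE
#' (clamped to [\code{tMin}, \code{tMax}]). The climb starts from
#' \code{start} (when given) plus \code{nStarts} random topologies,
#' and is deterministic for a fixed seed. Star-like input in which
#' every triple's counts are uniform is flagged as unresolved.
#'
#' @param counts A [tripletCounts()] object covering all triples.
#' @param start Optional starting tree (e.g. the STAR tree).
#' @param nStarts Number of additional random starting topologies.
#' @param seed Seed for the random starts.
#' @param tMin,tMax Branch-length clamp (coalescent units).
#' @return A rooted \code{phylo} topology with attributes
#'   \code{score} (log pseudo-likelihood) and \code{unresolved}
#'   (TRUE when the input cannot prefer any topology).
#' @export
mpestSearch <- function(counts, start = NULL, nStarts = 5L,
                        seed = NULL, tMin = 1e-6, tMax = 10) {
  taxa <- counts$taxa
  if (!is.null(seed)) set.seed(seed)
  unresolved <- all(counts$counts[, 1L] == counts$counts[, 2L] &
                      counts$counts[, 2L] == counts$counts[, 3L])
  starts <- list()
  if (!is.null(start)) {
    s <- start
    s$edge.length <- NULL
    if (!ape::is.binary(s) || !ape::is.rooted(s)) {
      s <- ape::multi2di(s)
    }
    starts[[1L]] <- s
  }
  for (i in seq_len(nStarts)) {
    starts[[length(starts) + 1L]] <- randomRootedTopology(taxa)
  }
  best <- NULL
  bestScore <- -Inf
  for (s in starts) {
    cur <- s
    curScore <- mpestProfileScore(cur, counts, tMin, tMax)
    repeat {
      nb <- rootedNNINeighbors(cur)
      if (!length(nb)) break
      sc <- vapply(nb, mpestProfileScore, numeric(1L),
                   counts = counts, tMin = tMin, tMax = tMax)
      i <- which.max(sc)
      if (sc[i] > curScore + 1e-9) {
        cur <- nb[[i]]
        curScore <- sc[i]
      } else break
    }
    if (curScore > bestScore) {
      bestScore <- curScore
      best <- cur
    }
  }
  attr(best, "score") <- bestScore
  attr(best, "unresolved") <- unresolved
  best
}
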