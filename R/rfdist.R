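## Robinson-Foulds topology comparison (rooted clade-set convention)
## and the tree-of-trees summary.

## Non-trivial clade set of a rooted tree: for every internal node
## except the root, the sorted tip labels it subtends, one string each.
cladeStrings <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "\r"),
                character(1L))
  out[-1L]  # first entry is the root clade (all tips)
}

## Non-trivial split set of an unrooted tree: bipartitions normalized
## to the side not containing the first taxon (alphabetically).
splitStrings <- function(tree) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1L]
  ut <- ape::unroot(tree)
  pp <- ape::prop.part(ut)
  plabs <- attr(pp, "labels")
  out <- vapply(pp, function(ix) {
    side <- plabs[ix]
    if (anchor %in% side) side <- setdiff(plabs, side)
    paste(sort(side), collapse = "\r")
  }, character(1L))
  out <- out[nchar(out) > 0]
  unique(out[vapply(strsplit(out, "\r", fixed = TRUE), length,
                    integer(1L)) >= 2L])
}

#' Robinson-Foulds distance between two trees
#'
#' Rooted comparison (the default): the symmetric difference of the two
#' trees' non-trivial clade sets, with maximum 2(n - 2) for n taxa.
#' Trees on different but overlapping leaf sets are pruned to the
#' intersection with a warning; disjoint leaf sets are an error.
#'
#' @param treeA,treeB \code{phylo} trees.
#' @param rooted Compare rooted clades (default) or unrooted splits
#'   (maximum 2(n - 3)).
#' @return A list: \code{rf}, \code{maxRf}, \code{percent}, \code{n}
#'   (taxa compared).
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' rfDistance(t1, t2)$percent   # 100
#' @export
rfDistance <- function(treeA, treeB, rooted = TRUE) {
  common <- intersect(treeA$tip.label, treeB$tip.label)
  if (!length(common)) {
    stop("rfDistance(): trees share no taxa")
  }
  if (length(common) < length(treeA$tip.label) ||
      length(common) < length(treeB$tip.label)) {
    warning("rfDistance(): pruning trees to ", length(common),
            " shared taxa")
    treeA <- ape::keep.tip(treeA, common)
    treeB <- ape::keep.tip(treeB, common)
  }
  n <- length(common)
  if (n < 3L) stop("rfDistance(): need at least 3 shared taxa")
  if (rooted) {
    a <- cladeStrings(treeA)
    b <- cladeStrings(treeB)
    maxRf <- 2L * (n - 2L)
  } else {
    a <- splitStrings(treeA)
    b <- splitStrings(treeB)
    maxRf <- 2L * (n - 3L)
  }
  rf <- length(setdiff(a, b)) + length(setdiff(b, a))
  list(rf = rf, maxRf = maxRf,
       percent = if (maxRf > 0) rf / maxRf * 100 else 0, n = n)
}

#' Mean bootstrap support across a tree
#'
#' Arithmetic mean of the internal-node support values stored in
#' \code{node.label}, with the root excluded.
#'
#' @param tree A \code{phylo} with numeric \code{node.label} supports.
#' @return Mean support.
#' @export
meanBootstrap <- function(tree) {
  if (is.null(tree$node.label)) {
    stop("meanBootstrap(): tree carries no support values")
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  rootNode <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  sup <- sup[-(rootNode - length(tree$tip.label))]
  sup <- sup[!is.na(sup)]
  if (!length(sup)) stop("meanBootstrap(): no supported internal nodes")
  mean(sup)
}

#' Tree-of-trees summary of alternative phylogenies
#'
#' Computes pairwise Robinson-Foulds percent distances among the input
#' trees (pruned to their common taxa) and clusters the trees
#' themselves by neighbor-joining, producing a tree whose leaves are
#' tree labels.
#'
#' @param trees List of \code{phylo} trees (>= 3).
#' @param labels Leaf labels of the output (default names of
#'   \code{trees}).
#' @param rooted Passed to [rfDistance()].
#' @return A list: \code{tree} (\code{phylo} over tree labels),
#'   \code{distances} (the RF percent matrix).
#' @export
metaTree <- function(trees, labels = names(trees), rooted = TRUE) {
  m <- length(trees)
  if (m < 3L) stop("metaTree(): need at least 3 trees")
  if (is.null(labels)) labels <- paste0("tree", seq_len(m))
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(common) < 3L) {
    stop("metaTree(): trees share fewer than 3 taxa")
  }
  trees <- lapply(trees, ape::keep.tip, tip = common)
  D <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      D[i, j] <- D[j, i] <- rfDistance(trees[[i]], trees[[j]],
                                       rooted = rooted)$percent
    }
  }
  list(tree = ape::nj(D), distances = D)
}
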