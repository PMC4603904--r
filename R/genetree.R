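## Distance-based gene-tree estimation with nonparametric bootstrap
## support — the desk-scale substitute for external ML gene trees.

alignmentToDNAbin <- function(alignment) {
  m <- alignmentToMatrix(alignment)
  ape::as.DNAbin(tolower(m))
}

njFromAlignment <- function(dna) {
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  bad <- !is.finite(dm)
  diag(bad) <- FALSE
  if (any(bad)) {
    finiteMax <- max(dm[is.finite(dm)], 0)
    dm[bad] <- 2 * finiteMax + 1
  }
  ape::nj(as.dist(dm))
}

#' Estimate a gene tree from one locus alignment
#'
#' Jukes-Cantor distances (pairwise deletion of gapped sites) resolved
#' by neighbor-joining, rooted by the declared outgroup — or by
#' midpoint when no outgroup is given, the clock-based default that
#' downstream rooted-tree methods (e.g. [starTree()]) rely on — with
#' optional
#' nonparametric (site-resampling) bootstrap support computed as the
#' percentage of replicates containing each clade of the point
#' estimate. Lowercase (soft-masked) bases participate uppercased;
#' external Newick gene trees can of course be supplied downstream
#' instead.
#'
#' @param alignment Named character vector (>= 3 rows, equal lengths)
#'   or character matrix.
#' @param outgroup Optional outgroup label(s) present in the alignment.
#' @param bootstrap Number of bootstrap replicates (0 = no support).
#' @param seed Seed for the bootstrap resampling.
#' @return A \code{phylo}; when bootstrapped, \code{node.label} holds
#'   percent support (root \code{NA}).
#' @export
estimateGeneTree <- function(alignment, outgroup = NULL,
                             bootstrap = 0L, seed = NULL) {
  m <- alignmentToMatrix(alignment)
  if (nrow(m) < 3L) {
    stop("estimateGeneTree(): need at least 3 sequences")
  }
  dna <- ape::as.DNAbin(tolower(m))
  tree <- njRoot(njFromAlignment(dna), outgroup)
  bootstrap <- as.integer(bootstrap)
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    L <- ncol(m)
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(L, L, replace = TRUE)
      bt <- njFromAlignment(ape::as.DNAbin(tolower(m[, cols,
                                                     drop = FALSE])))
      boots[[b]] <- njRoot(bt, outgroup)
    }
    class(boots) <- "multiPhylo"
    cl <- ape::prop.clades(tree, boots, rooted = ape::is.rooted(tree))
    cl[is.na(cl)] <- 0L
    sup <- round(cl / bootstrap * 100, 1)
    rootNode <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
    sup[rootNode - length(tree$tip.label)] <- NA_real_
    tree$node.label <- sup
  }
  tree
}
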