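## End-to-end driver: reads -> consensus -> orthologs -> masked
## alignments -> gene trees -> species trees.

#' Reference-anchored alignments of selected ortholog sets
#'
#' Consensus sequences are called in reference coordinates, so an
#' alignment is obtained by offsetting each sequence by its assembly
#' start and padding with gaps — a stand-in for an external aligner
#' that is exact whenever consensus calling introduced no indels.
#'
#' @param consensus A \code{ConsensusSet}.
#' @param orthology The [assessOrthology()] result for it.
#' @return Named list (locus) of named character vectors
#'   (sample to aligned sequence, equal lengths).
#' @export
orthologAlignments <- function(consensus, orthology) {
  tab <- consensusTable(consensus)
  key <- paste(tab$locus, paste(tab$sample, tab$cluster, sep = "|"),
               sep = "|")
  starts <- stats::setNames(tab$start, key)
  out <- list()
  for (locus in names(orthology$sets)) {
    a <- orthology$assignments
    sel <- a[a$locus == locus & a$selected, , drop = FALSE]
    seqs <- orthology$sets[[locus]]
    off <- starts[paste(locus, sel$name, sep = "|")][
      match(names(seqs), sel$sample)]
    off <- off - min(off)
    span <- max(off + nchar(seqs))
    out[[locus]] <- stats::setNames(vapply(seq_along(seqs), function(i) {
      paste0(strrep("-", off[i]), seqs[i],
             strrep("-", span - off[i] - nchar(seqs[i])))
    }, character(1L)), names(seqs))
  }
  out
}

#' Run the whole pipeline on a simulated dataset
#'
#' Merges read pairs, assembles per-sample consensus sequences,
#' assesses orthology, masks the per-locus alignments, estimates
#' distance-based gene trees, and estimates STAR and MP-EST species
#' trees.
#'
#' @param dataset An \code{AnchoredDataset}.
#' @param assemblyP,mergeP,maskP Stage parameter lists.
#' @param minSpeciesFraction Ortholog retention threshold.
#' @param bootstrap Gene-tree bootstrap replicates (0 = none).
#' @param outgroup Optional outgroup label(s).
#' @param seed Seed for gene-tree bootstraps and the MP-EST search.
#' @return A list: \code{consensus} (\code{ConsensusSet}),
#'   \code{orthology}, \code{alignments}, \code{masked} (list of
#'   [maskAlignment()] results), \code{alignmentSummaries},
#'   \code{geneTrees} (\code{multiPhylo}), \code{starTree},
#'   \code{mpestTree}.
#' @export
runPipeline <- function(dataset, assemblyP = assemblyParams(),
                        mergeP = mergeParams(),
                        maskP = maskParams(),
                        minSpeciesFraction = 0.5, bootstrap = 0L,
                        outgroup = NULL, seed = 1L) {
  consensus <- runAssembly(dataset, assemblyP, mergeP)
  orth <- assessOrthology(consensus,
                          nSpecies = length(
                            speciesTree(dataset)$tip.label),
                          minSpeciesFraction = minSpeciesFraction)
  alignments <- orthologAlignments(consensus, orth)
  masked <- lapply(alignments, maskAlignment, params = maskP)
  summaries <- lapply(masked, function(mk) {
    summarizeAlignment(mk$alignment)
  })
  usable <- vapply(masked, function(mk) {
    length(mk$alignment) >= 3L && nchar(mk$alignment[1L]) > 0L
  }, logical(1L))
  trees <- list()
  for (locus in names(masked)[usable]) {
    trees[[locus]] <- estimateGeneTree(
      masked[[locus]]$alignment, outgroup = outgroup,
      bootstrap = bootstrap,
      seed = derivedSeed(seed, match(locus, names(masked)))
    )
  }
  class(trees) <- "multiPhylo"
  star <- starTree(trees, outgroup = outgroup)
  counts <- tripletCounts(trees)
  mpest <- mpestSearch(counts, start = star, nStarts = 2L,
                       seed = derivedSeed(seed, 999983L))
  list(consensus = consensus, orthology = orth,
       alignments = alignments, masked = masked,
       alignmentSummaries = summaries, geneTrees = trees,
       starTree = star, mpestTree = mpest)
}
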