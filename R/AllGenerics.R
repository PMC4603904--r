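## Generics and accessors.

#' @rdname AnchoredDataset-class
#' @param object An object.
#' @export
setGeneric("speciesTree", function(object) standardGeneric("speciesTree"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("geneTrees", function(object) standardGeneric("geneTrees"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("readPairs", function(object) standardGeneric("readPairs"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("lociReferences", function(object) standardGeneric("lociReferences"))

#' @rdname AnchoredDataset-class
#' @export
setGeneric("trueSequences", function(object) standardGeneric("trueSequences"))

#' @rdname ConsensusSet-class
#' @param object An object.
#' @export
setGeneric("consensusTable", function(object) standardGeneric("consensusTable"))

#' @rdname ConsensusSet-class
#' @export
setGeneric("consensusSequences",
           function(object) standardGeneric("consensusSequences"))

#' @rdname ConsensusSet-class
#' @export
setGeneric("clusterReport", function(object) standardGeneric("clusterReport"))

#' @rdname ExperimentReport-class
#' @param object An object.
#' @export
setGeneric("experimentResults",
           function(object) standardGeneric("experimentResults"))

#' @rdname ExperimentReport-class
#' @export
setGeneric("experimentSummary",
           function(object) standardGeneric("experimentSummary"))

#' @rdname ExperimentReport-class
#' @export
setGeneric("plateauSize", function(object) standardGeneric("plateauSize"))

#' @describeIn AnchoredDataset-class True species tree (\code{phylo}).
setMethod("speciesTree", "AnchoredDataset", function(object) object@speciesTree)

#' @describeIn AnchoredDataset-class True gene trees (\code{multiPhylo}).
setMethod("geneTrees", "AnchoredDataset", function(object) object@geneTrees)

#' @describeIn AnchoredDataset-class Read-pair table including truth columns.
setMethod("readPairs", "AnchoredDataset", function(object) object@reads)

#' @describeIn AnchoredDataset-class Read-level truth table
#'   (read id to sample/locus/copy/position).
setMethod("truthTable", "AnchoredDataset", function(object) {
  object@reads[, c("id", "sample", "locus", "copy",
                   "fragStart", "fragLen", "strand")]
})

#' @describeIn AnchoredDataset-class Generating configuration.
setMethod("simConfig", "AnchoredDataset", function(object) object@config)

#' @describeIn AnchoredDataset-class Per-locus reference (probe-region)
#'   sequences.
setMethod("lociReferences", "AnchoredDataset", function(object) object@references)

#' @describeIn AnchoredDataset-class Per-locus list of true copy sequences.
setMethod("trueSequences", "AnchoredDataset", function(object) object@sequences)

#' @describeIn ConsensusSet-class Consensus metadata table.
setMethod("consensusTable", "ConsensusSet", function(object) object@table)

#' @describeIn ConsensusSet-class Named consensus strings
#'   (\code{"locus|sample|cluster"}).
setMethod("consensusSequences", "ConsensusSet", function(object) {
  stats::setNames(
    object@sequences,
    paste(object@table$locus, object@table$sample, object@table$cluster,
          sep = "|")
  )
})

#' @describeIn ConsensusSet-class Cluster report (pre-filter cluster
#'   counts and sizes).
setMethod("clusterReport", "ConsensusSet", function(object) object@clusterReport)

#' @describeIn ExperimentReport-class Per-replicate results.
setMethod("experimentResults", "ExperimentReport",
          function(object) object@results)

#' @describeIn ExperimentReport-class Per-size summary (mean RF, CV,
#'   mean bootstrap).
setMethod("experimentSummary", "ExperimentReport",
          function(object) object@summary)

#' @describeIn ExperimentReport-class Smallest subset size attaining the
#'   minimum CV, per method.
setMethod("plateauSize", "ExperimentReport", function(object) object@plateau)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSpecies, "species x", object@nLoci,
      "loci\n")
  cat("  locus length:", object@locusLengthRange[1L], "-",
      object@locusLengthRange[2L], "bp (mean ",
      object@meanLocusLength, ")\n", sep = "")
  cat("  model:", object@substitutionModel,
      "| subs/coal unit:", object@subsPerCoalUnit,
      "| branch scale:", object@internalBranchScale, "\n")
  cat("  reads: PE", object@readLength, ", fragments ",
      object@fragmentSizeRange[1L], "-", object@fragmentSizeRange[2L],
      " bp, coverage ", object@coverage, "x, error ",
      object@perBaseErrorRate, "\n", sep = "")
  cat("  missing:", object@missingFraction,
      "| paralog rate:", object@paralogRate,
      "| contaminant rate:", object@contaminantRate, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "AnchoredDataset", function(object) {
  cat("AnchoredDataset:", ape::Ntip(object@speciesTree), "species,",
      length(object@geneTrees), "loci,", nrow(object@reads),
      "read pairs\n")
  lens <- nchar(object@references)
  cat("  locus length:", min(lens), "-", max(lens),
      "bp (mean", round(mean(lens)), ")\n")
  cat("  copies simulated:", nrow(object@cells),
      "(", sum(object@cells$copy == "ortholog"), "ortholog )\n")
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet:", nrow(object@table), "consensus sequences over",
      length(unique(object@table$locus)), "loci and",
      length(unique(object@table$sample)), "samples\n")
  if (nrow(object@table)) {
    cat("  lengths:", min(object@table$length), "-",
        max(object@table$length), "bp; reads/cluster median",
        stats::median(object@table$nReads), "\n")
  }
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport:",
      paste(object@design$methods, collapse = "/"),
      "| sizes:", paste(object@design$sizes, collapse = ","),
      "| replicates:", object@design$replicates, "\n")
  print(object@summary, row.names = FALSE)
  cat("plateau (min-CV) size:",
      paste(names(object@plateau), object@plateau,
            sep = "=", collapse = ", "), "\n")
})
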