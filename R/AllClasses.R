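## S4 classes for the pipeline's central objects.

setOldClass("phylo")
setOldClass("multiPhylo")

#' Simulation configuration
#'
#' Parameters of the synthetic anchored-enrichment dataset generator.
#' Defaults emulate the study conditions the pipeline was designed for:
#' a 25-taxon radiation sequenced at PE150 from 150--350 bp fragments,
#' loci of 424--2156 bp (mean 1374 bp), and 1.5\% missing taxon-locus
#' cells. Gene-tree discordance arises from the multispecies coalescent
#' on the species tree's internal branches (coalescent units).
#'
#' @slot nSpecies Number of species (tree tips).
#' @slot nLoci Number of loci.
#' @slot locusLengthRange Integer pair: min and max locus length (bp).
#' @slot meanLocusLength Target mean locus length (bp); lengths are drawn
#'   from a log-normal truncated to \code{locusLengthRange} whose mean is
#'   tuned to this value.
#' @slot internalBranchScale Multiplier applied to species-tree branch
#'   lengths (coalescent units); smaller values mean more incomplete
#'   lineage sorting.
#' @slot substitutionModel \code{"JC"} or \code{"HKY"}.
#' @slot hkyKappa Transition/transversion rate ratio for HKY.
#' @slot baseFreqs Equilibrium base frequencies (A, C, G, T).
#' @slot subsPerCoalUnit Substitutions per site per coalescent unit;
#'   converts gene-tree branch lengths to expected substitutions.
#' @slot readLength Read length in bp (PE reads).
#' @slot fragmentSizeRange Integer pair: min and max sheared-fragment size.
#' @slot coverage Expected per-base sequencing depth per locus copy.
#' @slot perBaseErrorRate Per-base sequencing error probability.
#' @slot missingFraction Fraction of taxon-locus cells deleted outright.
#' @slot paralogRate Fraction of loci carrying a duplicated (paralogous)
#'   copy in every sample.
#' @slot contaminantRate Fraction of loci receiving a low-coverage
#'   diverged contaminant sequence in one sample.
#' @slot paralogDivergence Extra divergence (substitutions/site) on each
#'   side of the duplication node separating the two paralog copies.
#' @slot contaminantDivergence Divergence (substitutions/site) of the
#'   contaminant lineage from the locus root.
#' @slot contaminantCoverage Sequencing depth of contaminant copies
#'   (kept below the 10-read cluster filter by design).
#' @slot seed Integer seed driving every random stage.
#' @export
setClass("SimulationConfig",
  representation(
    nSpecies = "integer",
    nLoci = "integer",
    locusLengthRange = "integer",
    meanLocusLength = "numeric",
    internalBranchScale = "numeric",
    substitutionModel = "character",
    hkyKappa = "numeric",
    baseFreqs = "numeric",
    subsPerCoalUnit = "numeric",
    readLength = "integer",
    fragmentSizeRange = "integer",
    coverage = "numeric",
    perBaseErrorRate = "numeric",
    missingFraction = "numeric",
    paralogRate = "numeric",
    contaminantRate = "numeric",
    paralogDivergence = "numeric",
    contaminantDivergence = "numeric",
    contaminantCoverage = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0L)
  if (object@nSpecies < 3L) msg <- c(msg, "nSpecies must be >= 3")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  rates <- c(
    perBaseErrorRate = object@perBaseErrorRate,
    missingFraction = object@missingFraction,
    paralogRate = object@paralogRate,
    contaminantRate = object@contaminantRate
  )
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    msg <- c(msg, paste0(names(rates)[bad], " must lie in [0,1]"))
  }
  lr <- object@locusLengthRange
  if (length(lr) != 2L || lr[1L] > lr[2L]) {
    msg <- c(msg, "locusLengthRange must be an increasing pair")
  } else if (object@meanLocusLength < lr[1L] ||
             object@meanLocusLength > lr[2L]) {
    msg <- c(msg, "meanLocusLength must lie within locusLengthRange")
  }
  fr <- object@fragmentSizeRange
  if (length(fr) != 2L || fr[1L] > fr[2L]) {
    msg <- c(msg, "fragmentSizeRange must be an increasing pair")
  }
  if (!object@substitutionModel %in% c("JC", "HKY")) {
    msg <- c(msg, "substitutionModel must be 'JC' or 'HKY'")
  }
  if (length(object@baseFreqs) != 4L ||
      abs(sum(object@baseFreqs) - 1) > 1e-8) {
    msg <- c(msg, "baseFreqs must be 4 values summing to 1")
  }
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nSpecies,nLoci,locusLengthRange,meanLocusLength Dataset shape.
#' @param internalBranchScale,substitutionModel,hkyKappa,baseFreqs,subsPerCoalUnit
#'   Evolutionary-model settings.
#' @param readLength,fragmentSizeRange,coverage,perBaseErrorRate Sequencing
#'   settings.
#' @param missingFraction,paralogRate,contaminantRate,paralogDivergence,contaminantDivergence,contaminantCoverage
#'   Data-imperfection settings.
#' @param seed Integer seed.
#' @return A \code{SimulationConfig} object.
#' @seealso [simulateDataset()]
#' @examples
#' cfg <- simulationConfig(nSpecies = 5, nLoci = 4, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nSpecies = 25L,
                             nLoci = 377L,
                             locusLengthRange = c(424L, 2156L),
                             meanLocusLength = 1374,
                             internalBranchScale = 1,
                             substitutionModel = c("JC", "HKY"),
                             hkyKappa = 3,
                             baseFreqs = rep(0.25, 4),
                             subsPerCoalUnit = 0.015,
                             readLength = 150L,
                             fragmentSizeRange = c(150L, 350L),
                             coverage = 20,
                             perBaseErrorRate = 0.01,
                             missingFraction = 0.015,
                             paralogRate = 0,
                             contaminantRate = 0,
                             paralogDivergence = 0.15,
                             contaminantDivergence = 0.12,
                             contaminantCoverage = 3,
                             seed = 1L) {
  new("SimulationConfig",
    nSpecies = as.integer(nSpecies),
    nLoci = as.integer(nLoci),
    locusLengthRange = as.integer(locusLengthRange),
    meanLocusLength = as.numeric(meanLocusLength),
    internalBranchScale = as.numeric(internalBranchScale),
    substitutionModel = match.arg(substitutionModel),
    hkyKappa = as.numeric(hkyKappa),
    baseFreqs = as.numeric(baseFreqs),
    subsPerCoalUnit = as.numeric(subsPerCoalUnit),
    readLength = as.integer(readLength),
    fragmentSizeRange = as.integer(fragmentSizeRange),
    coverage = as.numeric(coverage),
    perBaseErrorRate = as.numeric(perBaseErrorRate),
    missingFraction = as.numeric(missingFraction),
    paralogRate = as.numeric(paralogRate),
    contaminantRate = as.numeric(contaminantRate),
    paralogDivergence = as.numeric(paralogDivergence),
    contaminantDivergence = as.numeric(contaminantDivergence),
    contaminantCoverage = as.numeric(contaminantCoverage),
    seed = as.integer(seed)
  )
}

#' Simulated anchored-enrichment dataset
#'
#' Holds every layer of one synthetic dataset: the true species tree,
#' the coalescent gene trees (one per locus), the true per-locus
#' sequences (including any paralog and contaminant copies), per-locus
#' reference ("probe-region") sequences, the paired reads with their
#' truth table, and the cell table recording which taxon-locus copies
#' exist.
#'
#' @slot speciesTree Rooted \code{phylo}; branch lengths in coalescent
#'   units.
#' @slot geneTrees \code{multiPhylo} list, one rooted gene tree per locus.
#' @slot sequences List (per locus) of named character vectors: the true
#'   ungapped sequence of each copy. Copy names are
#'   \code{"<sample>"}, \code{"<sample>|paralog"} or
#'   \code{"<sample>|contaminant"}.
#' @slot references Named character: per-locus reference sequence (the
#'   locus root sequence, playing the role of the probe-region
#'   reference taxon).
#' @slot reads data.frame of read pairs: \code{id, sample, locus, copy,
#'   fragStart, fragLen, strand, seq1, qual1, seq2, qual2}. The id plus
#'   the source columns form the read-level truth table.
#' @slot cells data.frame of simulated copies: \code{locus, sample, copy}.
#' @slot config The generating \code{SimulationConfig}.
#' @export
setClass("AnchoredDataset",
  representation(
    speciesTree = "phylo",
    geneTrees = "multiPhylo",
    sequences = "list",
    references = "character",
    reads = "data.frame",
    cells = "data.frame",
    config = "SimulationConfig"
  )
)

setValidity("AnchoredDataset", function(object) {
  msg <- character(0L)
  if (length(object@geneTrees) != length(object@sequences)) {
    msg <- c(msg, "one gene tree per locus is required")
  }
  need <- c("id", "sample", "locus", "copy", "seq1", "qual1", "seq2", "qual2")
  if (!all(need %in% names(object@reads))) {
    msg <- c(msg, "reads table is missing truth columns")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample, per-locus consensus sequences
#'
#' Output of the assembly stage: one IUPAC consensus per retained
#' assembly cluster, soft-masked (lowercase) where coverage is below
#' the soft-mask threshold, plus the cluster report.
#'
#' @slot table data.frame with one row per retained consensus:
#'   \code{locus, sample, cluster, nReads, length, meanCoverage, primary}.
#'   \code{primary} marks the largest cluster for each (locus, sample).
#' @slot sequences Character vector of consensus strings, parallel to
#'   \code{table} rows.
#' @slot clusterReport data.frame: \code{locus, sample, nClusters,
#'   readsPerCluster, nFiltered} over all clusters seen (before the
#'   minimum-read filter).
#' @export
setClass("ConsensusSet",
  representation(
    table = "data.frame",
    sequences = "character",
    clusterReport = "data.frame"
  )
)

setValidity("ConsensusSet", function(object) {
  if (nrow(object@table) != length(object@sequences)) {
    "table rows and sequences must be parallel"
  } else TRUE
})

#' Locus-subsampling experiment report
#'
#' Machine-readable result of the subsampling experiment: per
#' (method, subset size, replicate) the Robinson-Foulds percent distance
#' to the reference tree and the mean multilocus-bootstrap support, with
#' per-size means, coefficients of variation, and the CV-minimising
#' plateau size per method.
#'
#' @slot results data.frame: \code{method, size, replicate, rfPercent,
#'   meanBootstrap}.
#' @slot summary data.frame: \code{method, size, meanRF, cvRF,
#'   cvUndefined, meanBootstrap}.
#' @slot plateau Named numeric: per method, the smallest subset size
#'   attaining the minimum CV.
#' @slot design List of design settings used (sizes, replicates, seed,
#'   bootstrap replicates, methods).
#' @export
setClass("ExperimentReport",
  representation(
    results = "data.frame",
    summary = "data.frame",
    plateau = "numeric",
    design = "list"
  )
)
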