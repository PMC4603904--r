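## The locus-subsampling experiment: random locus subsets, replicate
## species trees, RF-vs-reference curves, coefficient-of-variation
## plateau detection, and multilocus-bootstrap support curves.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' A zero mean makes the CV undefined; by convention 0 is returned
#' with the attribute \code{undefined = TRUE}.
#'
#' @param values Numeric vector (>= 2 values).
#' @return The CV, with attribute \code{undefined}.
#' @examples
#' coefficientOfVariation(c(2, 4))   # sqrt(2)/3
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) {
    stop("coefficientOfVariation(): need at least 2 values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) {
    return(structure(0, undefined = s > 0))
  }
  structure(s / m, undefined = FALSE)
}

#' Draw a random locus subset
#'
#' Uniform sampling without replacement, deterministic per
#' (seed, replicate). Replicates draw independent subsets that may
#' overlap.
#'
#' @param loci Vector of locus identifiers (or an integer count).
#' @param size Subset size (<= number of loci).
#' @param seed Experiment seed.
#' @param replicate Replicate index (>= 1).
#' @return A vector of \code{size} sampled loci.
#' @export
subsampleLoci <- function(loci, size, seed, replicate = 1L) {
  if (length(loci) == 1L && is.numeric(loci)) loci <- seq_len(loci)
  if (size > length(loci)) {
    stop("subsampleLoci(): size ", size, " exceeds ", length(loci),
         " loci")
  }
  set.seed(derivedSeed(seed, 104729 * size + replicate))
  sample(loci, size)
}

#' Design of the locus-subsampling experiment
#'
#' @param sizes Subset sizes (default 3, 4, 5, 10, 25, 50, 100, 200).
#' @param replicates Random subsets per size (default 5).
#' @param seed Experiment seed.
#' @param methods Species-tree methods to run (\code{"STAR"},
#'   \code{"MPEST"}).
#' @param bootstrapReplicates Multilocus bootstrap replicates used for
#'   per-node support (0 disables support).
#' @param mpestStarts Random restarts of the MP-EST climb on top of
#'   the STAR starting tree (kept small because each subset replicate
#'   repeats the search; see the vignette).
#' @return A list describing the design.
#' @export
experimentDesign <- function(sizes = c(3L, 4L, 5L, 10L, 25L, 50L,
                                       100L, 200L),
                             replicates = 5L, seed = 1L,
                             methods = c("STAR", "MPEST"),
                             bootstrapReplicates = 25L,
                             mpestStarts = 2L) {
  stopifnot(replicates >= 1L, all(sizes >= 1L))
  methods <- match.arg(methods, several.ok = TRUE)
  list(sizes = sort(unique(as.integer(sizes))),
       replicates = as.integer(replicates), seed = as.integer(seed),
       methods = methods,
       bootstrapReplicates = as.integer(bootstrapReplicates),
       mpestStarts = as.integer(mpestStarts))
}

## STAR tree from precomputed per-tree rank matrices (taxa^2 x nLoci).
starFromRanks <- function(rankFlat, treeIdx, taxa, outgroup = NULL) {
  sub <- rankFlat[, treeIdx, drop = FALSE]
  mean_ <- rowMeans(sub, na.rm = TRUE)
  cnt <- rowSums(!is.na(sub))
  D <- matrix(2 * mean_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  bad <- matrix(cnt, length(taxa)) == 0 & row(D) != col(D)
  if (any(bad)) {
    stop("starFromRanks(): a taxon pair shares no gene tree in the ",
         "subset")
  }
  diag(D) <- 0
  njRoot(ape::nj(as.dist(D)), outgroup)
}

## Percent bootstrap support on `point` from a list of replicate trees.
bootstrapSupport <- function(point, boots) {
  class(boots) <- "multiPhylo"
  cl <- ape::prop.clades(point, boots,
                         rooted = ape::is.rooted(point))
  cl[is.na(cl)] <- 0L
  sup <- round(cl / length(boots) * 100, 1)
  rootNode <- setdiff(point$edge[, 1L], point$edge[, 2L])
  sup[rootNode - length(point$tip.label)] <- NA_real_
  point$node.label <- sup
  point
}

#' Run the locus-subsampling experiment
#'
#' For every method, subset size and replicate: draws a random locus
#' subset, estimates a species tree (STAR; MP-EST started from the
#' subset's STAR tree), records its rooted RF percent distance to the
#' reference tree, and attaches multilocus-bootstrap support (loci
#' resampled with replacement, species tree recomputed, per-clade
#' support on the point estimate). Per size it reports the mean RF
#' percent, the coefficient of variation of RF, and the mean
#' bootstrap; the plateau is the smallest size attaining the minimum
#' CV. The whole report is reproducible bit-for-bit under a fixed
#' seed.
#'
#' @param geneTrees \code{multiPhylo} or list of rooted gene trees
#'   (one per locus).
#' @param design An [experimentDesign()] list; sizes above the number
#'   of loci are dropped with a warning.
#' @param referenceTree Reference species tree; default is the STAR
#'   tree of all loci.
#' @param outgroup Optional outgroup label(s) used to root estimates.
#' @return An \code{ExperimentReport}.
#' @export
runExperiment <- function(geneTrees, design = experimentDesign(),
                          referenceTree = NULL, outgroup = NULL) {
  nLoci <- length(geneTrees)
  taxa <- sort(unique(unlist(lapply(geneTrees, `[[`, "tip.label"))))
  sizes <- design$sizes
  if (any(sizes > nLoci)) {
    warning("runExperiment(): dropping subset sizes above ", nLoci,
            " loci")
    sizes <- sizes[sizes <= nLoci]
  }
  if (!length(sizes)) stop("runExperiment(): no usable subset sizes")

  ## precompute per-tree STAR rank matrices and triplet categories
  rankFlat <- vapply(geneTrees, function(tr) {
    as.vector(starRankMatrix(tr, taxa))
  }, numeric(length(taxa)^2))
  counts <- if ("MPEST" %in% design$methods) {
    tripletCounts(geneTrees, taxa)
  } else NULL

  estimate <- function(method, treeIdx, startSeed) {
    if (method == "STAR") {
      starFromRanks(rankFlat, treeIdx, taxa, outgroup)
    } else {
      sub <- subsetTripletCounts(counts, treeIdx)
      st <- starFromRanks(rankFlat, treeIdx, taxa, outgroup)
      mpestSearch(sub, start = st, nStarts = design$mpestStarts,
                  seed = startSeed)
    }
  }

  if (is.null(referenceTree)) {
    referenceTree <- starFromRanks(rankFlat, seq_len(nLoci), taxa,
                                   outgroup)
  }

  rows <- list()
  for (method in design$methods) {
    for (size in sizes) {
      for (rep_ in seq_len(design$replicates)) {
        idx <- match(subsampleLoci(nLoci, size, design$seed, rep_),
                     seq_len(nLoci))
        point <- estimate(method, idx,
                          derivedSeed(design$seed,
                                    1000L * size + 10L * rep_ +
                                      match(method, design$methods)))
        rf <- rfDistance(point, referenceTree)
        mb <- NA_real_
        if (design$bootstrapReplicates > 0L) {
          set.seed(derivedSeed(design$seed,
                             7L + 1000L * size + 10L * rep_ +
                               match(method, design$methods)))
          boots <- lapply(seq_len(design$bootstrapReplicates),
                          function(b) {
                            bi <- sample(idx, length(idx),
                                         replace = TRUE)
                            estimate(method, bi, NULL)
                          })
          supported <- bootstrapSupport(point, boots)
          mb <- meanBootstrap(supported)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, size = size, replicate = rep_,
          rfPercent = rf$percent, rf = rf$rf,
          meanBootstrap = mb, stringsAsFactors = FALSE
        )
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  sumRows <- list()
  plateau <- c()
  for (method in design$methods) {
    for (size in sizes) {
      v <- results[results$method == method & results$size == size, ]
      cv <- coefficientOfVariation(v$rfPercent)
      sumRows[[paste(method, size)]] <- data.frame(
        method = method, size = size,
        meanRfPercent = mean(v$rfPercent),
        cvRf = as.numeric(cv), cvUndefined = attr(cv, "undefined"),
        meanBootstrap = mean(v$meanBootstrap),
        stringsAsFactors = FALSE
      )
    }
    ms <- do.call(rbind, sumRows[paste(method, sizes)])
    plateau[method] <- ms$size[which.min(ms$cvRf)]
  }
  summary_ <- do.call(rbind, sumRows)
  rownames(summary_) <- NULL

  new("ExperimentReport", results = results, summary = summary_,
      plateau = plateau,
      design = c(design, list(reference = "supplied-or-full-data-STAR",
                              nLoci = nLoci, sizesUsed = sizes)))
}
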