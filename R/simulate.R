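## Synthetic-data generator: species trees, MSC gene trees, sequences,
## paired reads, and the truth tables for every downstream stage.

#' Simulate a Yule species tree
#'
#' Draws a pure-birth (Yule) tree and scales its branch lengths, which
#' are interpreted downstream as coalescent units. Internal branch
#' lengths control the amount of incomplete lineage sorting the
#' coalescent gene-tree simulator produces.
#'
#' @param nSpecies Number of tips (>= 3).
#' @param internalBranchScale Multiplier applied to all branch lengths.
#' @param tipLabels Optional tip labels; defaults to \code{sp01, sp02, ...}.
#' @param seed Optional integer seed; if \code{NULL} the current RNG
#'   stream is used.
#' @return A rooted, binary, ultrametric \code{phylo} object.
#' @examples
#' tr <- simulateSpeciesTree(5, seed = 1)
#' @export
simulateSpeciesTree <- function(nSpecies, internalBranchScale = 1,
                                tipLabels = NULL, seed = NULL) {
  nSpecies <- as.integer(nSpecies)
  if (is.na(nSpecies) || nSpecies < 3L) {
    stop("simulateSpeciesTree(): nSpecies must be >= 3")
  }
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(nSpecies, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * internalBranchScale
  if (is.null(tipLabels)) {
    tipLabels <- sprintf("sp%02d", seq_len(nSpecies))
  }
  tr$tip.label <- tipLabels
  tr
}

## One coalescent gene tree within a species tree (one haploid lineage
## per species). Branch lengths of the species tree are coalescent
## units; within each species-tree branch, k lineages coalesce at rate
## k(k-1)/2 until the branch's parent is reached; at the root the
## process runs to a single lineage.
mscGeneTree <- function(sptree, heights = NULL, parentHeight = NULL,
                        childrenOf = NULL) {
  ntip <- length(sptree$tip.label)
  if (is.null(heights)) {
    depth <- ape::node.depth.edgelength(sptree)
    heights <- max(depth) - depth
  }
  if (is.null(parentHeight)) {
    parentHeight <- rep(Inf, ntip + sptree$Nnode)
    parentHeight[sptree$edge[, 2L]] <- heights[sptree$edge[, 1L]]
  }
  if (is.null(childrenOf)) {
    childrenOf <- split(sptree$edge[, 2L], sptree$edge[, 1L])
  }

  coalesceIn <- function(lins, t0, t1) {
    t <- t0
    while (length(lins) > 1L) {
      k <- length(lins)
      t <- t + stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t >= t1) break
      pair <- sample.int(k, 2L)
      a <- lins[[pair[1L]]]
      b <- lins[[pair[2L]]]
      merged <- list(
        nwk = paste0("(", a$nwk, ":", sprintf("%.10f", t - a$h),
                     ",", b$nwk, ":", sprintf("%.10f", t - b$h), ")"),
        h = t
      )
      lins <- c(lins[-pair], list(merged))
    }
    lins
  }

  rec <- function(node) {
    lins <- if (node <= ntip) {
      list(list(nwk = sptree$tip.label[node], h = heights[node]))
    } else {
      unlist(lapply(childrenOf[[as.character(node)]], rec),
             recursive = FALSE)
    }
    coalesceIn(lins, heights[node], parentHeight[node])
  }

  out <- rec(ntip + 1L)
  ape::read.tree(text = paste0(out[[1L]]$nwk, ";"))
}

#' Simulate coalescent gene trees within a species tree
#'
#' Generates one rooted gene tree per locus under the multispecies
#' coalescent, sampling one haploid lineage per species. For a rooted
#' triple with internal branch length t (coalescent units), the gene
#' trees match the species-tree triplet with probability
#' 1 - (2/3) exp(-t) and show each alternative with probability
#' (1/3) exp(-t).
#'
#' @param speciesTree Rooted \code{phylo} with branch lengths in
#'   coalescent units.
#' @param nLoci Number of gene trees to draw.
#' @param seed Optional integer seed.
#' @return A \code{multiPhylo} list of rooted gene trees, one tip per
#'   species.
#' @examples
#' sp <- simulateSpeciesTree(4, seed = 1)
#' gts <- simulateGeneTrees(sp, 10, seed = 2)
#' @export
simulateGeneTrees <- function(speciesTree, nLoci, seed = NULL) {
  if (is.null(speciesTree$edge.length)) {
    stop("simulateGeneTrees(): species tree needs branch lengths ",
         "(coalescent units)")
  }
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(speciesTree$tip.label)
  depth <- ape::node.depth.edgelength(speciesTree)
  heights <- max(depth) - depth
  parentHeight <- rep(Inf, ntip + speciesTree$Nnode)
  parentHeight[speciesTree$edge[, 2L]] <- heights[speciesTree$edge[, 1L]]
  childrenOf <- split(speciesTree$edge[, 2L], speciesTree$edge[, 1L])
  out <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    out[[i]] <- mscGeneTree(speciesTree, heights, parentHeight, childrenOf)
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate sequences along a gene tree
#'
#' Evolves aligned sequences along a gene tree under JC or HKY, with
#' branch lengths multiplied by \code{rate} to convert them to expected
#' substitutions per site (coalescent units times substitutions per
#' coalescent unit).
#'
#' @param geneTree Rooted \code{phylo}.
#' @param length Sequence length in bp (> 0).
#' @param model \code{"JC"} or \code{"HKY"}.
#' @param kappa HKY transition/transversion rate ratio.
#' @param baseFreqs Equilibrium base frequencies (A, C, G, T).
#' @param rate Substitutions per site per unit branch length.
#' @param rootSeq Optional root sequence as a character vector of bases;
#'   drawn from \code{baseFreqs} when \code{NULL}.
#' @param seed Optional integer seed.
#' @return Named character vector of uppercase sequences, one per tip,
#'   with the root sequence attached as \code{attr(, "rootSeq")}.
#' @export
simulateSequences <- function(geneTree, length, model = c("JC", "HKY"),
                              kappa = 3, baseFreqs = rep(0.25, 4),
                              rate = 1, rootSeq = NULL, seed = NULL) {
  model <- match.arg(model)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("simulateSequences(): length must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rootSeq)) {
    rootSeq <- sample(c("a", "c", "g", "t"), length,
                      replace = TRUE, prob = baseFreqs)
  } else {
    rootSeq <- tolower(rootSeq)
    if (base::length(rootSeq) != length) {
      stop("simulateSequences(): rootSeq length mismatch")
    }
  }
  Q <- if (model == "HKY") c(1, kappa, 1, 1, kappa, 1) else rep(1, 6)
  sim <- phangorn::simSeq(geneTree, l = length, Q = Q, bf = baseFreqs,
                          rate = rate, rootseq = rootSeq)
  m <- toupper(as.character(sim))
  out <- apply(m, 1L, paste, collapse = "")
  attr(out, "rootSeq") <- toupper(paste(rootSeq, collapse = ""))
  out
}

## JC point mutation of a base vector: each site substituted with
## probability (3/4)(1 - exp(-4 d / 3)) for divergence d subs/site.
mutateSequence <- function(baseVec, d) {
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(baseVec)) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    baseVec[hit] <- vapply(baseVec[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1L))
  }
  baseVec
}

## Apply sequencing errors and draw Phred qualities: errors get Phred
## 10-20, correct bases Phred 30-40, so quality-aware reconciliation in
## the merger is exercised.
addReadErrors <- function(seqs, errorRate) {
  bases <- c("A", "C", "G", "T")
  n <- length(seqs)
  outSeq <- character(n)
  outQual <- character(n)
  for (i in seq_len(n)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    m <- length(ch)
    err <- which(stats::runif(m) < errorRate)
    q <- sample(30:40, m, replace = TRUE)
    if (length(err)) {
      ch[err] <- vapply(ch[err], function(b) sample(setdiff(bases, b), 1L),
                        character(1L))
      q[err] <- sample(10:20, length(err), replace = TRUE)
    }
    outSeq[i] <- paste(ch, collapse = "")
    outQual[i] <- intToUtf8(q + 33L)
  }
  list(seq = outSeq, qual = outQual)
}

#' Simulate paired-end reads from source sequences
#'
#' Shears each source sequence into fragments of uniformly distributed
#' size, sequences both ends (read 2 reverse-complemented), applies
#' per-base substitution errors with matching Phred qualities, and
#' records the truth table (source copy, fragment position, strand).
#' Fragments shorter than the read length yield read-through reads of
#' the fragment length.
#'
#' @param sequences Named character vector of source sequences (one per
#'   copy; names become the \code{copy} truth column).
#' @param readLength Read length in bp.
#' @param fragmentSizeRange Integer pair of fragment sizes.
#' @param coverage Expected per-base depth; scalar or one value per
#'   sequence.
#' @param errorRate Per-base substitution error probability.
#' @param idPrefix Prefix for read ids.
#' @param seed Optional integer seed.
#' @return data.frame with columns \code{id, source, fragStart, fragLen,
#'   strand, seq1, qual1, seq2, qual2}.
#' @export
simulateReads <- function(sequences, readLength = 150L,
                          fragmentSizeRange = c(150L, 350L),
                          coverage = 20, errorRate = 0.01,
                          idPrefix = "r", seed = NULL) {
  if (!length(sequences)) stop("simulateReads(): no source sequences")
  if (!is.null(seed)) set.seed(seed)
  readLength <- as.integer(readLength)
  coverage <- rep_len(coverage, length(sequences))
  rows <- vector("list", length(sequences))
  for (s in seq_along(sequences)) {
    src <- sequences[s]
    len <- nchar(src)
    nFrag <- max(1L, as.integer(round(len * coverage[s] /
                                        (2 * readLength))))
    fl <- pmin(len, sample(seq.int(fragmentSizeRange[1L],
                                   fragmentSizeRange[2L]),
                           nFrag, replace = TRUE))
    start <- vapply(fl, function(f) sample.int(len - f + 1L, 1L), integer(1L))
    strand <- sample(c("+", "-"), nFrag, replace = TRUE)
    frag <- substr(rep(src, nFrag), start, start + fl - 1L)
    neg <- strand == "-"
    if (any(neg)) frag[neg] <- revComp(frag[neg])
    r1 <- substr(frag, 1L, pmin(readLength, fl))
    r2 <- revComp(substr(frag, pmax(1L, fl - readLength + 1L), fl))
    e1 <- addReadErrors(r1, errorRate)
    e2 <- addReadErrors(r2, errorRate)
    rows[[s]] <- data.frame(
      id = sprintf("%s_%s_%04d", idPrefix, names(sequences)[s],
                   seq_len(nFrag)),
      source = names(sequences)[s],
      fragStart = start, fragLen = fl, strand = strand,
      seq1 = e1$seq, qual1 = e1$qual, seq2 = e2$seq, qual2 = e2$qual,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Mean of a log-normal truncated to [a, b].
truncLnormMean <- function(mu, sdlog, a, b) {
  num <- exp(mu + sdlog^2 / 2) *
    (stats::pnorm((log(b) - mu - sdlog^2) / sdlog) -
       stats::pnorm((log(a) - mu - sdlog^2) / sdlog))
  den <- stats::plnorm(b, mu, sdlog) - stats::plnorm(a, mu, sdlog)
  num / den
}

#' Draw locus lengths from a truncated log-normal
#'
#' Lengths are drawn from a log-normal truncated to \code{range}, with
#' the location parameter tuned numerically so the truncated mean equals
#' \code{meanLength}. Only the range and mean of the target length
#' distribution are pinned down; the log-normal shape is the package's
#' choice of a realistic right-skewed locus-length law.
#'
#' @param n Number of lengths.
#' @param range Integer pair: minimum and maximum length.
#' @param meanLength Target mean.
#' @param sdlog Log-scale standard deviation.
#' @param seed Optional integer seed.
#' @return Integer vector of lengths in \code{[range[1], range[2]]}.
#' @export
drawLocusLengths <- function(n, range = c(424L, 2156L), meanLength = 1374,
                             sdlog = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- range[1L]
  b <- range[2L]
  mu <- stats::uniroot(function(m) truncLnormMean(m, sdlog, a, b) - meanLength,
                       interval = c(log(a), log(b)), tol = 1e-9)$root
  u <- stats::runif(n, stats::plnorm(a, mu, sdlog),
                    stats::plnorm(b, mu, sdlog))
  pmin(b, pmax(a, as.integer(round(stats::qlnorm(u, mu, sdlog)))))
}

#' Simulate a full anchored-enrichment dataset
#'
#' Runs the whole generator: Yule species tree, coalescent gene trees
#' (one per locus), locus lengths from the truncated log-normal,
#' sequences along each gene tree (the locus root sequence doubles as
#' the probe-region reference), optional paralog copies (a duplicated
#' locus diverged across an elongated duplication branch, present in
#' every sample of the affected loci), optional low-coverage diverged
#' contaminant copies, deletion of a fixed fraction of taxon-locus
#' cells, and paired-end reads with truth tables.
#'
#' @param config A \code{SimulationConfig}.
#' @return An \code{AnchoredDataset}.
#' @examples
#' cfg <- simulationConfig(nSpecies = 4, nLoci = 2,
#'                         locusLengthRange = c(300L, 500L),
#'                         meanLocusLength = 400, coverage = 5, seed = 7)
#' ds <- simulateDataset(cfg)
#' ds
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  sp <- simulateSpeciesTree(config@nSpecies, config@internalBranchScale)
  samples <- sp$tip.label
  nLoci <- config@nLoci
  locusIds <- sprintf("L%03d", seq_len(nLoci))
  gts <- simulateGeneTrees(sp, nLoci)
  lens <- drawLocusLengths(nLoci, config@locusLengthRange,
                           config@meanLocusLength)

  parLoci <- sample.int(nLoci, round(config@paralogRate * nLoci))
  conLoci <- sample.int(nLoci, round(config@contaminantRate * nLoci))

  ## missing taxon-locus cells (ortholog copies only), exact count
  nMiss <- round(config@missingFraction * nLoci * config@nSpecies)
  missIdx <- sample.int(nLoci * config@nSpecies, nMiss)
  missing <- data.frame(
    locus = locusIds[(missIdx - 1L) %/% config@nSpecies + 1L],
    sample = samples[(missIdx - 1L) %% config@nSpecies + 1L]
  )

  refs <- character(nLoci)
  names(refs) <- locusIds
  seqs <- vector("list", nLoci)
  names(seqs) <- locusIds
  bases <- c("A", "C", "G", "T")

  for (i in seq_len(nLoci)) {
    rootVec <- sample(bases, lens[i], replace = TRUE,
                      prob = config@baseFreqs)
    refs[i] <- paste(rootVec, collapse = "")
    tree <- gts[[i]]
    if (i %in% parLoci) {
      ## duplicated locus: both copies evolve along the same gene tree,
      ## joined by an elongated duplication branch
      dup <- tree
      dup$tip.label <- paste0(dup$tip.label, "|paralog")
      dupLen <- config@paralogDivergence / config@subsPerCoalUnit
      nwk <- paste0(
        "(", sub(";$", "", ape::write.tree(tree)), ":",
        sprintf("%.8f", dupLen), ",",
        sub(";$", "", ape::write.tree(dup)), ":",
        sprintf("%.8f", dupLen), ");"
      )
      tree <- ape::read.tree(text = nwk)
    }
    s <- simulateSequences(tree, lens[i],
                           model = config@substitutionModel,
                           kappa = config@hkyKappa,
                           baseFreqs = config@baseFreqs,
                           rate = config@subsPerCoalUnit,
                           rootSeq = rootVec)
    s <- stats::setNames(as.character(s), names(s))
    if (i %in% conLoci) {
      victim <- sample(samples, 1L)
      contam <- paste(mutateSequence(rootVec,
                                     config@contaminantDivergence),
                      collapse = "")
      s[paste0(victim, "|contaminant")] <- contam
    }
    drop <- missing$sample[missing$locus == locusIds[i]]
    if (length(drop)) s <- s[!names(s) %in% drop]
    seqs[[i]] <- s
  }

  readRows <- vector("list", nLoci)
  cellRows <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    s <- seqs[[i]]
    copyType <- ifelse(grepl("\\|paralog$", names(s)), "paralog",
                       ifelse(grepl("\\|contaminant$", names(s)),
                              "contaminant", "ortholog"))
    cov <- ifelse(copyType == "contaminant",
                  config@contaminantCoverage, config@coverage)
    rd <- simulateReads(s, config@readLength, config@fragmentSizeRange,
                        coverage = cov,
                        errorRate = config@perBaseErrorRate,
                        idPrefix = locusIds[i])
    rd$locus <- locusIds[i]
    rd$sample <- sub("\\|.*$", "", rd$source)
    rd$copy <- copyType[match(rd$source, names(s))]
    readRows[[i]] <- rd[, c("id", "sample", "locus", "copy", "fragStart",
                            "fragLen", "strand", "seq1", "qual1",
                            "seq2", "qual2")]
    cellRows[[i]] <- data.frame(
      locus = locusIds[i],
      sample = sub("\\|.*$", "", names(s)),
      copy = copyType, stringsAsFactors = FALSE
    )
  }

  new("AnchoredDataset",
      speciesTree = sp,
      geneTrees = gts,
      sequences = seqs,
      references = refs,
      reads = do.call(rbind, readRows),
      cells = do.call(rbind, cellRows),
      config = config)
}

#' Write a dataset's reads and references to FASTQ/FASTA
#'
#' Emits per-sample paired FASTQ files (Sanger Phred+33), a reference
#' FASTA of the per-locus probe-region sequences, and a tab-separated
#' read-level truth table.
#'
#' @param dataset An \code{AnchoredDataset}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
writeDatasetFiles <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rd <- dataset@reads
  files <- character(0L)
  for (s in unique(rd$sample)) {
    sub <- rd[rd$sample == s, ]
    for (mate in 1:2) {
      f <- file.path(dir, sprintf("%s_R%d.fastq", s, mate))
      seqc <- sub[[paste0("seq", mate)]]
      qual <- sub[[paste0("qual", mate)]]
      writeLines(paste0("@", sub$id, "/", mate, "\n", seqc, "\n+\n", qual),
                 f)
      files <- c(files, f)
    }
  }
  refFa <- file.path(dir, "references.fasta")
  writeLines(paste0(">", names(dataset@references), "\n",
                    dataset@references), refFa)
  truthTsv <- file.path(dir, "read_truth.tsv")
  utils::write.table(truthTable(dataset), truthTsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(files, refFa, truthTsv))
}
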