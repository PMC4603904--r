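test_that("species-tree simulation is reproducible and correctly sized", {
  a <- simulateSpeciesTree(10L, seed = 3L)
  b <- simulateSpeciesTree(10L, seed = 3L)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_equal(length(a$tip.label), 10L)
  expect_true(ape::is.rooted(a))
  expect_true(ape::is.binary(a))
  expect_true(ape::is.ultrametric(a, tol = 1e-6))
})

test_that("coalescent gene trees contain all species and deeper-than-species-root coalescences", {
  sp <- simulateSpeciesTree(6L, seed = 5L)
  gt <- simulateGeneTrees(sp, 25L, seed = 6L)
  expect_equal(length(gt), 25L)
  for (g in gt) {
    expect_setequal(g$tip.label, sp$tip.label)
    expect_true(ape::is.binary(g))
    ## gene-tree root must be at least as old as the species root
    expect_gte(max(ape::branching.times(g)) + 1e-9,
               max(ape::branching.times(sp)))
  }
})

test_that("triplet concordance follows the coalescent 1 - (2/3)exp(-t) law", {
  ## three species, internal branch t: the matching triplet appears
  ## with probability 1 - (2/3)exp(-t)
  for (t in c(0.5, 2)) {
    sp <- ape::read.tree(text = sprintf("((A:%f,B:%f):%f,C:%f);",
                                        1, 1, t, 1 + t))
    gt <- simulateGeneTrees(sp, 2000L, seed = 11L)
    counts <- tripletCounts(gt)
    pObs <- counts$counts[1L, 1L] / counts$n[1L]  # AB|C
    pExp <- 1 - (2 / 3) * exp(-t)
    se <- sqrt(pExp * (1 - pExp) / 2000)
    expect_lt(abs(pObs - pExp), 3.5 * se)
  }
})

test_that("locus lengths respect the truncation range and target mean", {
  set.seed(1)
  len <- drawLocusLengths(5000L, c(424L, 2156L), 1374L, seed = 8L)
  expect_true(all(len >= 424L & len <= 2156L))
  expect_lt(abs(mean(len) - 1374) / 1374, 0.02)
})

test_that("simulated datasets honor the configured missing-data fraction exactly", {
  cfg <- simulationConfig(nSpecies = 6L, nLoci = 10L,
                          locusLengthRange = c(300L, 500L),
                          meanLocusLength = 380L, coverage = 8,
                          missingFraction = 0.1, paralogRate = 0,
                          contaminantRate = 0, seed = 31L)
  ds <- simulateDataset(cfg)
  cells <- ds@cells
  orth <- cells[cells$copy == "ortholog", ]
  all_ <- expand.grid(sample = speciesTree(ds)$tip.label,
                      locus = names(lociReferences(ds)),
                      stringsAsFactors = FALSE)
  have <- paste(orth$sample, orth$locus)
  missingCells <- all_[!paste(all_$sample, all_$locus) %in% have, ]
  expect_equal(nrow(missingCells), round(0.1 * 6 * 10))
  ## no reads exist for missing cells
  tt <- truthTable(ds)
  for (i in seq_len(nrow(missingCells))) {
    expect_false(any(tt$sample == missingCells$sample[i] &
                       tt$locus == missingCells$locus[i]))
  }
})

test_that("read simulation produces paired, properly oriented, covering reads", {
  set.seed(2)
  template <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                    collapse = "")
  rd <- simulateReads(stats::setNames(template, "x"), readLength = 150L,
                      fragmentSizeRange = c(150L, 350L), coverage = 20,
                      errorRate = 0, idPrefix = "r", seed = 13L)
  expect_true(all(nchar(rd$seq1) <= 150L))
  expect_true(all(rd$fragLen >= 150L & rd$fragLen <= 350L))
  ## error-free reads reconstruct the template
  i <- 1L
  frag <- substr(template, rd$fragStart[i],
                 rd$fragStart[i] + rd$fragLen[i] - 1L)
  if (rd$strand[i] == "-") frag <- revComp(frag)
  expect_equal(rd$seq1[i], substr(frag, 1, nchar(rd$seq1[i])))
  expect_equal(rd$seq2[i],
               revComp(substr(frag, nchar(frag) - nchar(rd$seq2[i]) + 1L,
                              nchar(frag))))
  ## coverage close to target
  tot <- sum(nchar(rd$seq1) + nchar(rd$seq2))
  expect_gt(tot / 500, 15)
})

test_that("the full dataset generator is reproducible bit-for-bit", {
  cfg <- simulationConfig(nSpecies = 5L, nLoci = 4L,
                          locusLengthRange = c(300L, 400L),
                          meanLocusLength = 350L, coverage = 5,
                          seed = 77L)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(readPairs(d1), readPairs(d2))
  expect_identical(lociReferences(d1), lociReferences(d2))
  expect_identical(ape::write.tree(speciesTree(d1)),
                   ape::write.tree(speciesTree(d2)))
})

test_that("paralog copies diverge from the ortholog by the configured amount", {
  cfg <- simulationConfig(nSpecies = 5L, nLoci = 10L,
                          locusLengthRange = c(400L, 600L),
                          meanLocusLength = 500L, coverage = 5,
                          paralogRate = 1, contaminantRate = 0,
                          missingFraction = 0, seed = 41L)
  ds <- simulateDataset(cfg)
  seqs <- trueSequences(ds)
  locus <- names(seqs)[1L]
  s <- seqs[[locus]]
  samp <- ds@cells$sample[ds@cells$locus == locus &
                            ds@cells$copy == "ortholog"][1L]
  a <- strsplit(s[[samp]], "")[[1L]]
  b <- strsplit(s[[paste0(samp, "|paralog")]], "")[[1L]]
  d <- mean(a != b)
  ## two lineages separated by the duplication divergence (0.15
  ## expected substitutions/site on the duplication branch alone)
  expect_gt(d, 0.08)
  expect_lt(d, 0.45)
})
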