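randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("k-mer distance is a symmetric premetric with the right extremes", {
  set.seed(51)
  a <- randomSeq(100)
  b <- randomSeq(100)
  expect_equal(kmerDistance(a, a), 0)
  expect_equal(kmerDistance(a, b), kmerDistance(b, a))
  d <- kmerDistance(a, b)
  expect_gte(d, 0)
  expect_lte(d, 1)
  ## sequences over disjoint k-mer sets -> 1
  expect_equal(kmerDistance(strrep("A", 100), strrep("C", 100)), 1)
  expect_error(kmerDistance("ACGTACGTACGTACG", a), "at least 20")
})

test_that("one central substitution changes the distance exactly as brute-force set comparison predicts", {
  set.seed(52)
  a <- randomSeq(100)
  b <- a
  cur <- substr(b, 50, 50)
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  ## brute-force: tagged consecutive + spaced k-mer sets
  bruteSet <- function(s) {
    cons <- vapply(1:(nchar(s) - 19L), function(i) substr(s, i, i + 19L),
                   character(1L))
    sp <- vapply(1:(nchar(s) - 57L), function(i) {
      paste(strsplit(s, "")[[1L]][i + seq(0, 57, by = 3)],
            collapse = "")
    }, character(1L))
    unique(c(paste0("c:", cons), paste0("s:", sp)))
  }
  ka <- bruteSet(a)
  kb <- bruteSet(b)
  expected <- 1 - length(intersect(ka, kb)) / length(union(ka, kb))
  expect_equal(kmerDistance(a, b), expected)
})

test_that("soft-masked lowercase content participates uppercased", {
  set.seed(53)
  a <- randomSeq(60)
  expect_equal(kmerDistance(a, tolower(a)), 0)
})

test_that("constrained NJ splits paralogs into two one-per-sample clusters", {
  ## block-structured distances: copies of the same gene across
  ## samples are close; the two copies within a sample are far
  samples <- rep(c("s1", "s2", "s3", "s4"), 2L)
  n <- 8L
  D <- matrix(0.9, n, n)
  D[1:4, 1:4] <- 0.1
  D[5:8, 5:8] <- 0.1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0(samples, c(rep("a", 4),
                                                  rep("b", 4)))
  cl <- njClusterOrthologs(D, samples)
  expect_equal(length(cl), 2L)
  expect_setequal(sort(cl[[1L]]), if (1L %in% cl[[1L]]) 1:4 else 5:8)
  for (g in cl) expect_false(anyDuplicated(samples[g]) > 0)
})

test_that("clusters partition the input even when all joins are forbidden", {
  samples <- c("s1", "s1", "s1")
  D <- matrix(0.2, 3, 3)
  diag(D) <- 0
  cl <- njClusterOrthologs(D, samples)
  expect_equal(length(cl), 3L)
  expect_setequal(unlist(cl), 1:3)
})

test_that("species-fraction retention is inclusive at exactly 50 %", {
  set.seed(54)
  base <- randomSeq(120)
  mut <- function(s, d) paste(
    AnchorCoal:::mutateSequence(strsplit(s, "")[[1L]], d),
    collapse = "")
  ## 5 of 10 species -> fraction exactly 0.5 -> retained
  seqs5 <- vapply(1:5, function(i) mut(base, 0.01), character(1L))
  tab5 <- data.frame(locus = "L1", sample = paste0("s", 1:5),
                     cluster = 1L, stringsAsFactors = FALSE)
  o5 <- assessOrthology(list(table = tab5, sequences = seqs5),
                        nSpecies = 10L)
  expect_equal(length(o5$sets), 1L)
  expect_equal(o5$summary$speciesFraction, 0.5)
  ## 4 of 10 -> dropped
  o4 <- assessOrthology(list(table = tab5[1:4, ],
                             sequences = seqs5[1:4]), nSpecies = 10L)
  expect_equal(length(o4$sets), 0L)
  expect_equal(o4$summary$nRetained, 0L)
})

test_that("orthology assessment keeps single-copy loci whole and separates paralog copies", {
  set.seed(55)
  nSpecies <- 6L
  base <- randomSeq(200)
  paraBase <- paste(AnchorCoal:::mutateSequence(
    strsplit(base, "")[[1L]], 0.2), collapse = "")
  mut <- function(s) paste(AnchorCoal:::mutateSequence(
    strsplit(s, "")[[1L]], 0.02), collapse = "")
  tab <- data.frame(
    locus = "L1",
    sample = rep(paste0("s", 1:nSpecies), 2L),
    cluster = rep(1:2, each = nSpecies),
    stringsAsFactors = FALSE
  )
  seqs <- c(vapply(1:nSpecies, function(i) mut(base), character(1L)),
            vapply(1:nSpecies, function(i) mut(paraBase),
                   character(1L)))
  orth <- assessOrthology(list(table = tab, sequences = seqs),
                          nSpecies = nSpecies)
  a <- orth$assignments
  expect_equal(max(a$cluster), 2L)
  ## each cluster holds exactly one copy family
  for (ci in unique(a$cluster)) {
    names_ <- a$name[a$cluster == ci]
    copyTag <- sub("^.*\\|", "", names_)
    expect_equal(length(unique(copyTag)), 1L)
  }
})
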