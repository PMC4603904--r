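randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("the spaced index enumerates exactly the brute-force spaced 20-mers", {
  set.seed(31)
  refs <- c(L1 = randomSeq(120), L2 = randomSeq(90))
  idx <- buildSpacedIndex(refs)
  p <- assemblyParams()
  ## brute force: at offset o (0-based), characters o + 0,3,...,57
  for (locus in names(refs)) {
    s <- refs[[locus]]
    span <- (p$kmerLen - 1L) * p$spacing + 1L
    expected <- vapply(0:(nchar(s) - span), function(o) {
      paste(strsplit(s, "")[[1L]][o + seq(1L, by = 3L,
                                          length.out = 20L)],
            collapse = "")
    }, character(1L))
    got <- idx$kmers[idx$kmers$locus == locus, ]
    expect_equal(got$kmer[order(got$offset)], expected)
  }
})

test_that("index excludes k-mers spanning N and rejects duplicate locus ids", {
  s <- randomSeq(120)
  substr(s, 60, 60) <- "N"
  idx <- buildSpacedIndex(c(A = s))
  ## offsets whose spaced pattern covers position 60 (1-based):
  ## o + 1 + 3j = 60 for some j in 0..19 -> excluded
  bad0 <- (59 - seq(0, 57, by = 3))
  bad0 <- bad0[bad0 >= 0 & bad0 <= nchar(s) - 58]
  expect_true(all(!idx$kmers$offset[idx$kmers$locus == "A"] %in% bad0))
  expect_equal(nrow(idx$kmers), (120 - 58 + 1) - length(bad0))
  expect_error(buildSpacedIndex(c(A = s, A = s)), "unique")
})

test_that("two loci sharing a 20-mer region keep both postings", {
  set.seed(32)
  shared <- randomSeq(58)
  refs <- c(X = paste0(randomSeq(40), shared, randomSeq(40)),
            Y = paste0(shared, randomSeq(60)))
  idx <- buildSpacedIndex(refs)
  sharedKmer <- idx$kmers$kmer[idx$kmers$locus == "Y" &
                                 idx$kmers$offset == 0L]
  hits <- idx$kmers[idx$kmers$kmer == sharedKmer, ]
  expect_setequal(hits$locus, c("X", "Y"))
})

test_that("error-free reads map to their true reference position on either strand", {
  set.seed(33)
  refs <- c(L1 = randomSeq(400), L2 = randomSeq(400))
  idx <- buildSpacedIndex(refs)
  r <- substr(refs[["L2"]], 101, 250)
  mp <- mapReads(c(r, revComp(r)), idx)
  expect_equal(mp$status, c("mapped", "mapped"))
  expect_equal(mp$locus, c("L2", "L2"))
  expect_equal(mp$pos, c(100L, 100L))
  expect_equal(mp$seq[2L], r)  # reported in reference orientation
})

test_that("the preliminary 17-of-20 spaced threshold tolerates exactly 3 seed mismatches", {
  set.seed(34)
  ref <- c(L = randomSeq(300))
  idx <- buildSpacedIndex(ref)
  flipAt <- function(s, pos) {
    for (p_ in pos) {
      cur <- substr(s, p_, p_)
      substr(s, p_, p_) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
    }
    s
  }
  base <- substr(ref[["L"]], 51, 170)
  ## mutate 3 of the spaced positions of the first seed (offsets
  ## 1, 4, 7 within the read): still a preliminary hit somewhere and
  ## the confirmation threshold is untouched (3 mismatches in 120 bp)
  r3 <- flipAt(base, c(1, 4, 7))
  expect_equal(mapReads(r3, idx)$status, "mapped")
  ## corrupt every third base across the whole read: every spaced seed
  ## loses >3 positions and confirmation drops below 55 % matches
  rAll <- flipAt(base, seq(1, 120, by = 2))
  expect_equal(mapReads(rAll, idx)$status, "unmapped")
})

test_that("confirmation demands strictly more than 55 matches per 100 aligned bases", {
  ## construct a read whose first 58 bp equal the reference (perfect
  ## seed) but whose remainder is unrelated: 58 + x matches in 100
  set.seed(35)
  ref <- c(L = randomSeq(300))
  idx <- buildSpacedIndex(ref)
  good <- substr(ref[["L"]], 1, 58)
  junk <- function(template) {
    ## anti-match: shift every base so nothing matches
    chartr("ACGT", "CAGT", template)  # A<->C swap, G,T fixed points
  }
  ## 58 guaranteed matches within the first 100 bases; the other 42
  ## match only where the junk coincides (G/T positions)
  restRef <- substr(ref[["L"]], 59, 158)
  rest <- chartr("ACGT", "CATG", restRef)   # all four changed
  r <- paste0(good, rest)
  got <- mapReads(r, idx)
  expect_equal(got$status, "mapped")
  expect_equal(got$score, 58L)
  ## trim the matching prefix below the pro-rata proportion: 55/100 of
  ## a 58-bp overlap needs >31.9 matches; give it 20
  short <- paste0(substr(ref[["L"]], 1, 20),
                  chartr("ACGT", "CATG", substr(ref[["L"]], 21, 58)))
  expect_equal(mapReads(short, idx)$status, "unmapped")
})

test_that("a cross-locus best-score tie is discarded as ambiguous", {
  set.seed(36)
  shared <- randomSeq(150)
  refs <- c(A = paste0(shared, randomSeq(100)),
            B = paste0(shared, randomSeq(100)))
  idx <- buildSpacedIndex(refs)
  mp <- mapReads(substr(shared, 11, 120), idx)
  expect_equal(mp$status, "ambiguous")
})

test_that("de novo 60-mer extension recruits reads beyond the reference but not 59-base matches", {
  set.seed(37)
  ref <- randomSeq(200)
  extension <- randomSeq(150)
  truth <- paste0(ref, extension)
  idx <- buildSpacedIndex(c(L = ref))
  ## read A overlaps reference end and extension start
  readA <- substr(truth, 141, 260)
  ## read B lies fully in the extension, sharing >= 60 bp with read A
  readB <- substr(truth, 181, 300)
  ## read C shares only 59 bases with read B's end
  readC <- substr(truth, 242, 360)
  mp <- mapReads(c(readA, readB, readC), idx,
                 ids = c("A", "B", "C"))
  expect_equal(mp$status, c("mapped", "unmapped", "unmapped"))
  ext <- extendAssembly(
    mapped = mp[mp$status == "mapped", c("id", "seq", "locus", "pos")],
    unmapped = mp[mp$status == "unmapped", c("id", "seq")]
  )
  expect_true("B" %in% ext$mapped$id)
  expect_equal(ext$mapped$pos[ext$mapped$id == "B"], 180L)
  ## C shares 60-mers with B (B spans 181..300, C starts at 242:
  ## 59 shared bases with... ) — C overlaps B by 300-242+1 = 59 bases
  expect_false("C" %in% ext$mapped$id)
  expect_true("C" %in% ext$unmapped$id)
})

test_that("extension also recruits reverse-complemented reads", {
  set.seed(38)
  ref <- randomSeq(200)
  extension <- randomSeq(120)
  truth <- paste0(ref, extension)
  idx <- buildSpacedIndex(c(L = ref))
  readA <- substr(truth, 141, 260)
  readB <- revComp(substr(truth, 181, 300))
  mp <- mapReads(c(readA), idx, ids = "A")
  ext <- extendAssembly(mp[, c("id", "seq", "locus", "pos")],
                        data.frame(id = "B", seq = readB,
                                   stringsAsFactors = FALSE))
  expect_true("B" %in% ext$mapped$id)
  expect_equal(ext$mapped$seq[ext$mapped$id == "B"],
               substr(truth, 181, 300))
})

test_that("60-mer co-occurrence clustering separates ortholog and paralog reads", {
  set.seed(39)
  orth <- randomSeq(300)
  para <- AnchorCoal:::mutateSequence(strsplit(orth, "")[[1L]], 0.15)
  para <- paste(para, collapse = "")
  mkReads <- function(src, n, prefix) {
    start <- sample.int(nchar(src) - 119L, n, replace = TRUE)
    data.frame(id = paste0(prefix, seq_len(n)),
               seq = substr(rep(src, n), start, start + 119L),
               pos = start - 1L, stringsAsFactors = FALSE)
  }
  reads <- rbind(mkReads(orth, 15L, "o"), mkReads(para, 15L, "p"))
  cl <- clusterReads(reads)
  big <- Filter(function(x) nrow(x$reads) >= 10L, cl)
  expect_equal(length(big), 2L)
  for (g in big) {
    pref <- substr(g$reads$id, 1, 1)
    expect_equal(length(unique(pref)), 1L)  # no mixing
  }
})

test_that("cluster filtering removes clusters below 10 reads at the exact boundary", {
  mk <- function(n) list(reads = data.frame(id = as.character(seq_len(n)),
                                            seq = "A", pos = 0L,
                                            gapPos = NA_integer_))
  kept <- filterClusters(list(mk(9L), mk(10L), mk(11L)))
  expect_equal(vapply(kept, function(x) nrow(x$reads), integer(1L)),
               c(10L, 11L))
})

test_that("consensus calling follows the binomial error model worked examples", {
  p <- assemblyParams()
  mkCluster <- function(bases) {
    list(reads = data.frame(id = as.character(seq_along(bases)),
                            seq = bases, pos = 0L,
                            gapPos = NA_integer_,
                            stringsAsFactors = FALSE))
  }
  ## A x9 + G x1: P(X >= 1 | n = 10, p = 0.1) = 0.651 >= 0.05 -> 'A'
  c1 <- callConsensus(mkCluster(c(rep("A", 9), "G")), p)
  expect_equal(c1$sequence, "A")
  ## A x5 + G x5: P(X >= 5 | 10, 0.1) = 0.00163 < 0.05 -> IUPAC 'R'
  c2 <- callConsensus(mkCluster(c(rep("A", 5), rep("G", 5))), p)
  expect_equal(c2$sequence, "R")
  ## coverage 4 (< 5): soft-masked lowercase
  c3 <- callConsensus(mkCluster(rep("A", 4)), p)
  expect_equal(c3$sequence, "a")
  ## coverage 5 boundary: uppercase
  c4 <- callConsensus(mkCluster(rep("A", 5)), p)
  expect_equal(c4$sequence, "A")
})

test_that("uncovered interior columns become gap characters in the consensus", {
  reads <- data.frame(id = c("a", "b"),
                      seq = c("AAAAA", "CCCCC"),
                      pos = c(0L, 8L), gapPos = NA_integer_,
                      stringsAsFactors = FALSE)
  cl <- list(reads = reads)
  cons <- callConsensus(cl, assemblyParams())
  expect_equal(cons$sequence, "aaaaa---ccccc")
})

test_that("alignment refinement rescues a shifted read and never lowers agreement", {
  set.seed(40)
  template <- randomSeq(120)
  reads <- data.frame(
    id = paste0("r", 1:6),
    seq = c(rep(substr(template, 1, 100), 5),
            substr(template, 11, 110)),
    pos = c(rep(0L, 5), 14L),  # read 6 misplaced by +4
    gapPos = NA_integer_, stringsAsFactors = FALSE
  )
  cl <- list(reads = reads)
  before <- AnchorCoal:::clusterAgreement(reads)
  p <- assemblyParams(refineMaxShift = 4L)
  out <- refineAlignment(cl, p)
  after <- AnchorCoal:::clusterAgreement(out$reads)
  expect_gte(after, before)
  expect_equal(out$reads$pos[6L], 10L)
})

test_that("perfect clusters are fixed points of refinement", {
  set.seed(41)
  template <- randomSeq(150)
  reads <- data.frame(
    id = paste0("r", 1:8),
    seq = substring(template, 1:8, 100 + (1:8)),
    pos = 0:7, gapPos = NA_integer_, stringsAsFactors = FALSE
  )
  out <- refineAlignment(list(reads = reads), assemblyParams())
  expect_equal(out$reads$pos, 0:7)
  expect_true(all(is.na(out$reads$gapPos)))
})
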