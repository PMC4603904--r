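test_that("STAR rank distances match hand-computed averages", {
  tAB <- ape::read.tree(text = "((A,B),C);")
  tAC <- ape::read.tree(text = "((A,C),B);")
  tBC <- ape::read.tree(text = "((B,C),A);")
  ## a single tree: root rank 2, cherry rank 1
  D1 <- starDistanceMatrix(list(tAB))
  expect_equal(D1["A", "B"], 2)
  expect_equal(D1["A", "C"], 4)
  expect_equal(D1["B", "C"], 4)
  expect_true(isSymmetric(D1))
  expect_equal(diag(D1), c(A = 0, B = 0, C = 0))
  ## 6 : 2 : 2 mixture — D(A,B) = 2 * (6*1 + 4*2)/10 = 2.8,
  ## D(A,C) = 2 * (6*2 + 2*1 + 2*2)/10 = 3.6 = D(B,C)
  trees <- c(rep(list(tAB), 6), rep(list(tAC), 2), rep(list(tBC), 2))
  Dm <- starDistanceMatrix(trees)
  expect_equal(Dm["A", "B"], 2.8)
  expect_equal(Dm["A", "C"], 3.6)
  expect_equal(Dm["B", "C"], 3.6)
})

test_that("taxa missing from some trees are averaged over the trees containing them", {
  t1 <- ape::read.tree(text = "((A,B),C);")
  t2 <- ape::read.tree(text = "(((A,B),C),D);")
  D <- starDistanceMatrix(list(t1, t2))
  ## A,B: ranks 1 (t1) and 1 (t2); A,C: 2 and 2; A,D only in t2: 3
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["A", "D"], 6)
  ## a pair never co-occurring is an error
  t3 <- ape::read.tree(text = "((A,B),E);")
  expect_error(starDistanceMatrix(list(t1, t3)),
               "share no gene tree")
})

test_that("STAR recovers the majority topology and is exact on concordant input", {
  tAB <- ape::read.tree(text = "(((A,B),C),D);")
  tAC <- ape::read.tree(text = "(((A,C),B),D);")
  same <- starTree(rep(list(tAB), 20), outgroup = "D")
  expect_equal(rfDistance(same, tAB)$rf, 0L)
  mix <- starTree(c(rep(list(tAB), 12), rep(list(tAC), 8)),
                  outgroup = "D")
  expect_equal(rfDistance(mix, tAB)$rf, 0L)
})

test_that("without an outgroup the STAR tree is midpoint-rooted at the true root", {
  set.seed(91)
  sp <- simulateSpeciesTree(8L, seed = 3L)
  gts <- simulateGeneTrees(sp, 100L, seed = 4L)
  withOg <- starTree(gts)
  expect_true(ape::is.rooted(withOg))
  ## concordance sanity: rank distances from many loci recover a tree
  ## close to the species tree
  expect_lte(rfDistance(withOg, sp)$rf, 2L)
})

test_that("triplet categories agree with a prune-and-inspect oracle", {
  set.seed(92)
  taxa <- paste0("t", 1:5)
  for (i in 1:20) {
    tr <- oracleRandomRootedTree(5L, taxa)
    tc <- tripletCounts(list(tr), taxa)
    for (r in seq_len(nrow(tc$tripleIdx))) {
      trip <- taxa[tc$tripleIdx[r, ]]
      cherry <- oracleTripletCherry(tr, trip)
      expectedCat <- if (is.null(cherry)) 0L else {
        pairs <- list(trip[c(1, 2)], trip[c(1, 3)], trip[c(2, 3)])
        which(vapply(pairs, function(p) setequal(p, cherry),
                     logical(1L)))
      }
      expect_equal(tc$categories[r, 1L], as.integer(expectedCat))
    }
  }
})

test_that("subset triplet counts equal recounting the subset from scratch", {
  set.seed(93)
  trees <- replicate(15, oracleRandomRootedTree(6L), simplify = FALSE)
  taxa <- sort(trees[[1L]]$tip.label)
  full <- tripletCounts(trees, taxa)
  idx <- c(2L, 5L, 11L, 14L)
  sub <- subsetTripletCounts(full, idx)
  direct <- tripletCounts(trees[idx], taxa)
  expect_equal(sub$counts, direct$counts)
  expect_equal(sub$n, direct$n)
})

test_that("the closed-form branch MLE maximizes the trinomial likelihood", {
  for (p in c(0.4, 0.6, 0.9, 0.99)) {
    nm <- round(1000 * p)
    na_ <- 1000 - nm
    ll <- function(t) {
      nm * log(1 - (2 / 3) * exp(-t)) + na_ * log((1 / 3) * exp(-t))
    }
    numeric_ <- stats::optimize(ll, c(1e-6, 10), maximum = TRUE)$maximum
    expect_equal(mpestBranchMLE(nm / 1000), numeric_, tolerance = 1e-4)
    expect_equal(mpestBranchMLE(nm / 1000),
                 -log(1.5 * (1 - nm / 1000)), tolerance = 1e-9)
  }
  ## clamping
  expect_equal(mpestBranchMLE(1 / 3), 1e-6)   # t = 0 -> floor
  expect_equal(mpestBranchMLE(1), 10)         # infinite -> ceiling
  expect_equal(mpestBranchMLE(0.9), -log(0.15))
})

test_that("the pseudo-likelihood equals a per-triple multinomial product computed independently", {
  set.seed(94)
  sp <- ape::read.tree(text = "((A:3,B:3):1,(C:2,D:2):2);")
  trees <- c(replicate(8, ape::read.tree(text = "((A,B),(C,D));"),
                       simplify = FALSE),
             replicate(2, ape::read.tree(text = "((A,C),(B,D));"),
                       simplify = FALSE))
  tc <- tripletCounts(trees, c("A", "B", "C", "D"))
  got <- mpestScore(sp, tc)
  ## oracle: prune the species tree to each triple; t = cherry depth
  ## minus root depth; each gene tree contributes log of its
  ## category's probability
  oracle <- 0
  taxa <- tc$taxa
  for (r in seq_len(nrow(tc$tripleIdx))) {
    trip <- taxa[tc$tripleIdx[r, ]]
    sub <- ape::keep.tip(sp, trip)
    cherry <- oracleTripletCherry(sp, trip)
    dep <- ape::node.depth.edgelength(sub)
    t <- max(dep[(length(trip) + 1):(length(trip) + sub$Nnode)]) -
      min(dep[(length(trip) + 1):(length(trip) + sub$Nnode)])
    pm <- 1 - (2 / 3) * exp(-t)
    pa <- (1 / 3) * exp(-t)
    for (g in trees) {
      gc <- oracleTripletCherry(g, trip)
      oracle <- oracle + log(if (setequal(gc, cherry)) pm else pa)
    }
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("fully concordant counts drive the score of the truth to zero at long branches", {
  truth <- ape::read.tree(text = "(((A,B),C),D);")
  tc <- tripletCounts(rep(list(truth), 10), c("A", "B", "C", "D"))
  long <- ape::compute.brlen(truth, 10)
  expect_gt(mpestScore(long, tc), -1e-3)
  wrong <- ape::compute.brlen(
    ape::read.tree(text = "(((A,C),B),D);"), 10)
  expect_lt(mpestScore(wrong, tc), mpestScore(long, tc) - 10)
})

test_that("the MP-EST search recovers a concordant topology and stays there", {
  set.seed(95)
  truth <- oracleRandomRootedTree(8L)
  tc <- tripletCounts(rep(list(truth), 25), sort(truth$tip.label))
  est <- mpestSearch(tc, nStarts = 3L, seed = 17L)
  expect_equal(rfDistance(est, truth)$rf, 0L)
  expect_false(attr(est, "unresolved"))
  ## starting from the truth does not move away
  est2 <- mpestSearch(tc, start = truth, nStarts = 0L)
  expect_equal(rfDistance(est2, truth)$rf, 0L)
})

test_that("star-like uniform counts are flagged unresolved", {
  trees <- list(ape::read.tree(text = "((A,B),C);"),
                ape::read.tree(text = "((A,C),B);"),
                ape::read.tree(text = "((B,C),A);"))
  tc <- tripletCounts(trees, c("A", "B", "C"))
  est <- mpestSearch(tc, nStarts = 2L, seed = 1L)
  expect_true(attr(est, "unresolved"))
})
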