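## Independent oracles used across the suite. These deliberately avoid
## the package's own code paths.

## Upper-tail binomial probability by direct pmf summation.
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

## Non-trivial clade set of a rooted tree by plain recursion over the
## edge matrix (no ape helpers).
oracleCladeSet <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    sort(unlist(lapply(kids[[as.character(node)]], desc)))
  }
  internal <- unique(tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  sets <- lapply(setdiff(internal, root), function(nd) desc(nd))
  vapply(sets, paste, character(1L), collapse = "\r")
}

## Rooted RF by clade-set symmetric difference.
oracleRF <- function(a, b) {
  ca <- oracleCladeSet(a)
  cb <- oracleCladeSet(b)
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

## All k-mer start positions of `pat` in `s` via brute-force substring
## comparison.
oracleKmerSet <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  unique(km[!grepl("[^ACGT]", km)])
}

## Random rooted binary tree over n taxa (pure R, no branch lengths).
oracleRandomRootedTree <- function(n, labels = paste0("t", seq_len(n))) {
  nodes <- as.list(sample(labels))
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    merged <- paste0("(", nodes[[i[1L]]], ",", nodes[[i[2L]]], ")")
    nodes <- c(nodes[-i], merged)
  }
  ape::read.tree(text = paste0(nodes[[1L]], ";"))
}

## Restrict a rooted tree to a taxon triple and name the cherry pair,
## via the clade structure only.
oracleTripletCherry <- function(tree, triple) {
  sub <- ape::keep.tip(tree, triple)
  cl <- oracleCladeSet(sub)
  two <- cl[vapply(strsplit(cl, "\r"), length, integer(1L)) == 2L]
  if (length(two) != 1L) return(NULL)  # unresolved
  strsplit(two, "\r")[[1L]]
}
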