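## Small shared helpers: complements, Phred codecs, k-mer sets, IUPAC codes.

IUPAC_CODE <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement that preserves case and IUPAC ambiguity
#' codes (soft-masked lowercase stays lowercase).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
revComp <- function(x) {
  comp <- chartr(
    "ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
    "TGCAKYWSRMBDHVNtgcakywsrmbdhvn", x
  )
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

revString <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

## Phred+33 (Sanger) codecs
phredToChar <- function(q) {
  vapply(q, function(qi) intToUtf8(qi + 33L), character(1L))
}

charToPhred <- function(s) {
  lapply(s, function(si) utf8ToInt(si) - 33L)
}

#' Upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p). Used both by the read-merging
#' overlap criterion and by the consensus sequencing-error test.
#'
#' @param k Number of successes (matches, or non-majority bases).
#' @param n Number of trials.
#' @param p Per-trial success probability.
#' @return Upper-tail probability, a number in \[0, 1\].
#' @export
binomUpperTail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) {
    stop("binomUpperTail(): k must satisfy 0 <= k <= n")
  }
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

## All consecutive k-mers of a string (character vector of length n-k+1).
consecutiveKmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0L))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Spaced k-mers: k positions taken every `spacing` bases, so each k-mer
## spans (k-1)*spacing + 1 consecutive bases of the source.
spacedKmers <- function(x, k, spacing) {
  span <- (k - 1L) * spacing + 1L
  n <- nchar(x)
  if (n < span) return(character(0L))
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  pat <- seq(0L, by = spacing, length.out = k)
  starts <- seq_len(n - span + 1L)
  idx <- outer(starts, pat, "+")
  matrix(ch[t(idx)], nrow = k) |>
    apply(2L, paste, collapse = "")
}

## IUPAC code for a set of observed bases (subset of A,C,G,T).
iupacCode <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_CODE[key]
  if (is.na(code)) stop("no IUPAC code for base set: ", key)
  unname(code)
}

## Draw a child seed below 2^31 from the current RNG stream.
childSeed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

#' Deterministic child seed derived from a parent seed and an index
#'
#' Hashes a parent seed and an index into a child seed in
#' \code{[0, 2^31 - 1)}, independent of the RNG state, so that
#' stages and replicates of a run get reproducible, decorrelated
#' seeds from a single top-level seed.
#'
#' @param seed Parent integer seed.
#' @param index Integer index distinguishing the child streams.
#' @return An integer seed below \code{2^31}.
#' @examples
#' derivedSeed(1L, 1L)
#' @export
derivedSeed <- function(seed, index) {
  m <- 2147483647
  x <- ((seed %% m) * 48271 + (index %% m)) %% m
  x <- (x * 69621 + 12345) %% m
  as.integer(x)
}
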