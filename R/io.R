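## Minimal case-preserving FASTA/FASTQ text I/O. Soft-masked
## (lowercase) consensus bases must survive a round trip, which rules
## out containers that normalize case.

#' Read a FASTA file preserving case
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
readFasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("readFasta(): no FASTA headers in ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1L),
                 collapse = "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

#' Write sequences to FASTA preserving case
#'
#' @param seqs Named character vector.
#' @param path File path.
#' @param width Line-wrap width.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts,
                         pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path File path.
#' @return data.frame with columns \code{id, seq, qual}.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("readFastq(): truncated FASTQ in ", path)
  }
  i <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             seq = lines[i + 1L], qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns \code{id, seq, qual}.
#' @param path File path.
#' @export
writeFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rbind(paste0("@", reads$id), reads$seq, "+",
                     reads$qual)), con)
  invisible(path)
}
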