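#' Read lengths of small RNA reads
#'
#' Lengths of adapter-trimmed reads from FASTA or FASTQ (optionally
#' gzipped; format auto-detected from the first record). Reads shorter than
#' \code{minLen} are dropped and the count reported, honoring the usual
#' trimming minimum-length convention. An optional id filter restricts the
#' profile to a caller-supplied read subset (e.g. genome-aligned reads from
#' an external aligner).
#'
#' @param path FASTA/FASTQ file
#' @param minLen minimum read length kept (default 15)
#' @param keepIds optional character vector of read ids to keep
#' @return integer vector of read lengths
#' @export
readLengths <- function(path, minLen = 15L, keepIds = NULL) {
  if (!file.exists(path)) stop("no such reads file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (!length(first)) {
    warning("empty reads file: ", path)
    return(integer())
  }
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  reads <- Biostrings::readDNAStringSet(path, format = fmt)
  if (!is.null(keepIds)) {
    ids <- sub("\\s.*$", "", names(reads))
    reads <- reads[ids %in% keepIds]
  }
  len <- Biostrings::width(reads)
  dropped <- sum(len < minLen)
  if (dropped > 0) {
    message(dropped, " read(s) shorter than ", minLen, " nt dropped")
  }
  len[len >= minLen]
}

#' Small RNA size-class profile
#'
#' Read-abundance histogram over a length range (duplicate reads counted
#' per occurrence). Fractions are of the in-range total; out-of-range reads
#' count toward \code{total_seen} only.
#'
#' @param lengths integer read lengths (from \code{\link{readLengths}})
#' @param rangeLo,rangeHi inclusive length range (default 20-25 nt)
#' @return list: \code{profile} data.frame (length, count, fraction),
#'   \code{total_in_range}, \code{total_seen}
#' @export
sizeProfile <- function(lengths, rangeLo = 20L, rangeHi = 25L) {
  if (!length(lengths)) stop("no reads supplied")
  if (rangeLo > rangeHi) stop("rangeLo must not exceed rangeHi")
  lens <- rangeLo:rangeHi
  counts <- vapply(lens, function(l) sum(lengths == l), numeric(1))
  inRange <- sum(counts)
  if (inRange == 0) {
    warning("no reads within [", rangeLo, ", ", rangeHi, "] nt")
  }
  list(profile = data.frame(
         length = lens, count = as.integer(counts),
         fraction = if (inRange > 0) counts / inRange else
           rep(0, length(lens))),
       total_in_range = as.integer(inRange),
       total_seen = length(lengths))
}
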