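#' Genome occupancy of a peak set
#'
#' Fraction of the genome covered by the merged peak set.
#'
#' @param peaks \code{GRanges}
#' @param genome \code{DNAStringSet} or named chromosome lengths
#' @return fraction in [0,1]
#' @export
occupancyFraction <- function(peaks, genome) {
  sl <- if (is(genome, "DNAStringSet")) genomeSeqlengths(genome) else genome
  .checkKnownChroms(peaks, sl)
  coveredBp(peaks) / sum(as.numeric(sl))
}

#' Element-peak overlap count and percentage
#'
#' Counts each element once if it intersects at least \code{minBp} bases of
#' any peak (strand-ignorant, half-open boundary semantics: an element
#' ending where a peak begins does not overlap it).
#'
#' @param elements,peaks \code{GRanges}
#' @param minBp minimum overlap in bp (default 1)
#' @return list: \code{n_overlapping}, \code{n_total}, \code{percent}
#'   (100 * n/total, rounded half-away-from-zero to 2 decimals)
#' @export
elementOverlap <- function(elements, peaks, minBp = 1L) {
  if (!length(elements)) stop("element set is empty")
  if (minBp < 1L) stop("minBp must be >= 1")
  hit <- GenomicRanges::countOverlaps(elements, peaks,
                                      minoverlap = as.integer(minBp),
                                      ignore.strand = TRUE) > 0
  n <- sum(hit); total <- length(elements)
  pct <- floor(100 * n / total * 100 + 0.5) / 100
  list(n_overlapping = n, n_total = total, percent = pct)
}

#' Build a bedtools-fisher style contingency table
#'
#' 2x2 table for element-peak association: n11 = elements overlapping at
#' least one peak; n12 = elements overlapping none; n21 = peaks overlapping
#' no element; n22 = remaining "genome slots", estimated as
#' round(G / mean interval length) minus the other three cells (floored at
#' 0 with a warning), with the mean taken over elements and peaks combined.
#' The n22 estimator is deliberately isolated here so alternative
#' constructions can be swapped in.
#'
#' @param elements,peaks nonempty \code{GRanges}
#' @param genome \code{DNAStringSet} or named chromosome lengths
#' @return list with n11, n12, n21, n22, genome_bp, mean_interval_bp
#' @export
buildContingency <- function(elements, peaks, genome) {
  if (!length(elements) || !length(peaks)) {
    stop("both interval sets must be nonempty")
  }
  sl <- if (is(genome, "DNAStringSet")) genomeSeqlengths(genome) else genome
  G <- sum(as.numeric(sl))
  eHit <- IRanges::overlapsAny(elements, peaks, ignore.strand = TRUE)
  pHit <- IRanges::overlapsAny(peaks, elements, ignore.strand = TRUE)
  n11 <- sum(eHit); n12 <- sum(!eHit); n21 <- sum(!pHit)
  lbar <- mean(c(GenomicRanges::width(elements),
                 GenomicRanges::width(peaks)))
  n22 <- round(G / lbar) - n11 - n12 - n21
  if (n22 < 0) {
    warning("genome smaller than the interval union; n22 floored at 0")
    n22 <- 0
  }
  list(n11 = n11, n12 = n12, n21 = n21, n22 = as.integer(n22),
       genome_bp = G, mean_interval_bp = lbar)
}

#' Exact Fisher test on a 2x2 table
#'
#' Conditional exact test via the hypergeometric distribution with the
#' table's margins fixed. \code{p_greater} is the upper tail (enrichment);
#' \code{p_two_sided} sums all tables whose probability does not exceed the
#' observed table's (with a 1e-7 relative slack for ties, the standard
#' convention). Probabilities are accumulated from log-space hypergeometric
#' masses.
#'
#' @param n11,n12,n21,n22 nonnegative cell counts; alternatively pass a 2x2
#'   matrix as \code{n11}
#' @return list: \code{table}, \code{odds_ratio} (sample OR; NA when a
#'   margin is 0), \code{p_greater}, \code{p_two_sided}
#' @export
fisherExactTest <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL) {
  if (is.matrix(n11)) {
    m <- n11; n11 <- m[1, 1]; n12 <- m[1, 2]; n21 <- m[2, 1]; n22 <- m[2, 2]
  } else if (is.list(n11)) {
    l <- n11; n11 <- l$n11; n12 <- l$n12; n21 <- l$n21; n22 <- l$n22
  }
  cells <- c(n11, n12, n21, n22)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be nonnegative")
  }
  if (sum(cells) == 0) stop("all-zero contingency table")
  m1 <- n11 + n12   # row 1 margin
  m2 <- n21 + n22   # row 2 margin
  k <- n11 + n21    # column 1 margin
  support <- max(0, k - m2):min(m1, k)
  logp <- stats::dhyper(support, m1, m2, k, log = TRUE)
  pmf <- exp(logp)
  pGreater <- sum(pmf[support >= n11])
  obs <- pmf[support == n11]
  pTwo <- sum(pmf[pmf <= obs * (1 + 1e-7)])
  orr <- if (n12 == 0 || n21 == 0) {
    if (n11 > 0 && n22 > 0) Inf else NA_real_
  } else n11 * n22 / (n12 * n21)
  if (m1 == 0 || m2 == 0 || k == 0 || (n12 + n22) == 0) orr <- NA_real_
  list(table = matrix(cells, 2, 2, byrow = TRUE),
       odds_ratio = orr,
       p_greater = min(1, pGreater),
       p_two_sided = min(1, pTwo))
}
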