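#' Read a genome FASTA
#'
#' Loads a multi-record FASTA into a \code{DNAStringSet}, folding soft-masked
#' (lowercase) bases to uppercase. Lowercase runs are retained per chromosome
#' in \code{metadata(x)$softMask} but play no role in any downstream
#' statistic. Record names are truncated at the first whitespace.
#'
#' @param path FASTA file (plain or gzipped)
#' @param controlContig optional name of an unmethylated control contig
#'   (e.g. the chloroplast); recorded in \code{mcols(x)$organelle}
#' @return \code{DNAStringSet} with unique names, alphabet restricted to
#'   A,C,G,T,N; \code{mcols(x)$organelle} flags the control contig
#' @export
readGenome <- function(path, controlContig = NA_character_) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  chars <- as.character(seqs)
  mask <- lapply(chars, function(s) {
    lc <- gregexpr("[acgtn]+", s)[[1]]
    if (lc[1] == -1L) IRanges::IRanges() else
      IRanges::IRanges(start = as.integer(lc),
                       width = attr(lc, "match.length"))
  })
  up <- toupper(chars)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("non-IUPAC character (outside A,C,G,T,N) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(up)
  names(out) <- names(seqs)
  GenomeInfoDb::seqlengths(out)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    organelle = names(out) %in% controlContig
  )
  S4Vectors::metadata(out) <- list(softMask = mask,
                                   controlContig = controlContig)
  out
}

#' Seqinfo helper: named chromosome lengths of a genome
#' @param genome \code{DNAStringSet}
#' @return named integer vector
#' @export
genomeSeqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## Core trinucleotide classifier. Accepts strings of length <= 3 (truncated at
## a sequence end) and strings containing N; these yield context "undefined"
## unless the context is still decidable (CG needs only the second base).
.classifyTriplet <- function(tri) {
  tri <- toupper(tri)
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  H <- c("A", "C", "T")
  W <- c("A", "T")
  context <- rep("undefined", length(tri))
  context[b2 == "G"] <- "CG"
  context[b2 %in% H & b3 == "G"] <- "CHG"
  context[b2 %in% H & b3 %in% H] <- "CHH"
  symmetry <- rep(NA_character_, length(tri))
  symmetry[context == "CG"] <- "CG-dyad"
  symmetry[context == "CHG" & b2 %in% W] <- "CWG-dyad"
  symmetry[context == "CHG" & b2 == "C"] <- "CCG"
  symmetry[context == "CHH"] <- "CHH"
  cwa <- context == "CHH" & b2 %in% W & b3 == "A"
  list(context = context, symmetry = symmetry, cwa = cwa)
}

#' Classify a cytosine trinucleotide context
#'
#' Classifies trinucleotides read 5'->3' on the cytosine's own strand into the
#' plant methylation contexts CG, CHG and CHH (H = A, C or T), with the
#' subcontext splits used for symmetry and pathway analysis: CHG is divided
#' into the palindromic CWG (CAG/CTG, W = A or T) and the non-palindromic CCG;
#' CHH trinucleotides are flagged CWA (second base A/T, third base A), the
#' signature of CMT2 targeting. A trinucleotide containing N is classified
#' only where still decidable (CGN is CG; CNG and CANN are undefined).
#'
#' @param triplet character vector of trinucleotides, first base C
#' @return \code{data.frame} with columns \code{subcontext}, \code{context}
#'   (CG/CHG/CHH/undefined), \code{symmetry} (CG-dyad, CWG-dyad, CCG, CHH or
#'   NA), and logical \code{cwa}
#' @examples
#' classifyContext(c("CAG", "CTA", "CGN"))
#' @export
classifyContext <- function(triplet) {
  triplet <- toupper(as.character(triplet))
  if (any(nchar(triplet) != 3L)) {
    stop("each triplet must have exactly 3 bases")
  }
  if (any(substr(triplet, 1L, 1L) != "C")) {
    stop("first base of every triplet must be C")
  }
  cl <- .classifyTriplet(triplet)
  data.frame(subcontext = triplet, context = cl$context,
             symmetry = cl$symmetry, cwa = cl$cwa,
             stringsAsFactors = FALSE)
}

#' Enumerate all cytosine sites of a genome
#'
#' Emits one site per cytosine on either strand: every C of the reference
#' (Watson) and every G (a C on Crick). Sites are width-1 ranges at the
#' Watson coordinate of the base, the allc convention; a minus-strand site's
#' trinucleotide is read 5'->3' on the reverse complement. Sites within 2 bp
#' of their strand's 3' sequence end, or whose context is not decidable
#' because of an N, carry context "undefined" and are excluded from every
#' downstream statistic.
#'
#' @param genome \code{DNAStringSet} from \code{\link{readGenome}}
#' @return stranded width-1 \code{GRanges} with mcols \code{subcontext},
#'   \code{context}, \code{symmetry}, \code{cwa}; seqlengths set
#' @export
cytosineSites <- function(genome) {
  stopifnot(is(genome, "DNAStringSet"))
  per <- lapply(seq_along(genome), function(i) {
    s <- as.character(genome[[i]])
    L <- nchar(s)
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    wpos <- which(bases == "C")
    cpos <- which(bases == "G")
    wtri <- if (length(wpos)) substring(s, wpos, pmin(wpos + 2L, L)) else
      character()
    ctri <- if (length(cpos)) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
        substring(s, pmax(cpos - 2L, 1L), cpos))))
    } else character()
    pos <- c(wpos, cpos)
    strand <- rep(c("+", "-"), c(length(wpos), length(cpos)))
    tri <- c(wtri, ctri)
    cl <- .classifyTriplet(tri)
    ## truncated trinucleotides (strand's 3' end) are always undefined
    cl$context[nchar(tri) < 3L] <- "undefined"
    cl$symmetry[nchar(tri) < 3L] <- NA_character_
    cl$cwa[nchar(tri) < 3L] <- FALSE
    GenomicRanges::GRanges(
      seqnames = factor(rep(names(genome)[i], length(pos)),
                        levels = names(genome)),
      ranges = IRanges::IRanges(start = pos, width = 1L),
      strand = strand,
      subcontext = tri, context = cl$context,
      symmetry = cl$symmetry, cwa = cl$cwa
    )
  })
  gr <- sort(do.call(c, per), ignore.strand = TRUE)
  GenomeInfoDb::seqlengths(gr) <- genomeSeqlengths(genome)
  gr
}

#' Pair symmetric cytosine dyads
#'
#' Pairs each Watson-strand CG with the Crick CG one base downstream, and
#' each Watson CWG (CAG/CTG) with the Crick CWG two bases downstream. CCG
#' sites are not palindromic at the cytosine and are excluded by default
#' (the base opposite a CCG cytosine's G is itself a CG-context cytosine);
#' \code{includeCCG = TRUE} additionally pairs each Watson CCG with the
#' opposite-strand cytosine two bases downstream for sensitivity analysis.
#'
#' @param sites stranded \code{GRanges} with mcols \code{subcontext} and
#'   \code{context} (from \code{\link{cytosineSites}} or a
#'   \code{\link{Methylome}})
#' @param includeCCG also pair CCG sites with their opposite-strand cytosine
#' @return \code{data.frame} with integer columns \code{watson}, \code{crick}
#'   (indices into \code{sites}) and \code{kind} (CG, CWG, or CCG)
#' @export
pairDyads <- function(sites, includeCCG = FALSE) {
  m <- S4Vectors::mcols(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  str <- as.character(GenomicRanges::strand(sites))
  key <- paste(chrom, pos, str)
  ## CG dyads: Watson CG at p, Crick CG at p+1
  wcg <- which(str == "+" & m$context == "CG")
  icg <- match(paste(chrom[wcg], pos[wcg] + 1L, "-"), key)
  okcg <- !is.na(icg) & m$context[icg] == "CG"
  okcg[is.na(okcg)] <- FALSE
  cg <- data.frame(watson = wcg[okcg], crick = icg[okcg],
                   kind = rep("CG", sum(okcg)), stringsAsFactors = FALSE)
  ## CWG dyads: Watson CAG/CTG at p, Crick CWG at p+2
  wcwg <- which(str == "+" & m$subcontext %in% c("CAG", "CTG"))
  icwg <- match(paste(chrom[wcwg], pos[wcwg] + 2L, "-"), key)
  okw <- !is.na(icwg) & m$subcontext[icwg] %in% c("CAG", "CTG")
  okw[is.na(okw)] <- FALSE
  cwg <- data.frame(watson = wcwg[okw], crick = icwg[okw],
                    kind = rep("CWG", sum(okw)), stringsAsFactors = FALSE)
  out <- rbind(cg, cwg)
  if (includeCCG) {
    wccg <- which(str == "+" & m$subcontext == "CCG")
    iccg <- match(paste(chrom[wccg], pos[wccg] + 2L, "-"), key)
    okc <- !is.na(iccg)
    out <- rbind(out, data.frame(watson = wccg[okc], crick = iccg[okc],
                                 kind = rep("CCG", sum(okc)),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Tile a genome into nonoverlapping windows
#'
#' @param genome \code{DNAStringSet}, or a named vector of chromosome lengths
#' @param width window width in bp (>= 1); the final window on each
#'   chromosome is truncated and flagged \code{partial}
#' @return \code{GRanges} with logical mcol \code{partial}
#' @export
tileWindows <- function(genome, width) {
  if (length(width) != 1L || is.na(width) || width < 1) {
    stop("window width must be a single integer >= 1")
  }
  sl <- if (is(genome, "DNAStringSet")) genomeSeqlengths(genome) else genome
  width <- as.integer(width)
  per <- lapply(names(sl), function(ch) {
    starts <- seq.int(1L, sl[[ch]], by = width)
    GenomicRanges::GRanges(
      factor(rep(ch, length(starts)), levels = names(sl)),
      IRanges::IRanges(starts, end = pmin(starts + width - 1L, sl[[ch]])))
  })
  gr <- do.call(c, per)
  GenomeInfoDb::seqlengths(gr) <- sl
  S4Vectors::mcols(gr)$partial <- GenomicRanges::width(gr) < width
  gr
}

.checkKnownChroms <- function(x, genome) {
  known <- if (is(genome, "DNAStringSet")) names(genome) else names(genome)
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(x))), known)
  if (length(bad)) {
    stop("interval(s) on unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Interval arithmetic helpers
#'
#' Thin strand-ignorant wrappers over \pkg{GenomicRanges}:
#' \code{intervalsOverlap} reports, per interval in \code{a}, whether it
#' intersects any interval in \code{b} (adjacent intervals do not overlap);
#' \code{mergeIntervals} unions touching or overlapping intervals per
#' chromosome; \code{coveredBp} is the total merged length.
#'
#' @param a,b,x \code{GRanges}
#' @param genome optional \code{DNAStringSet} or named lengths; supplying it
#'   makes intervals on unknown chromosomes an error
#' @return logical vector / \code{GRanges} / integer
#' @export
intervalsOverlap <- function(a, b, genome = NULL) {
  if (!is.null(genome)) { .checkKnownChroms(a, genome); .checkKnownChroms(b, genome) }
  IRanges::overlapsAny(a, b, ignore.strand = TRUE)
}

#' @rdname intervalsOverlap
#' @export
mergeIntervals <- function(x, genome = NULL) {
  if (!is.null(genome)) .checkKnownChroms(x, genome)
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' @rdname intervalsOverlap
#' @export
coveredBp <- function(x, genome = NULL) {
  sum(as.numeric(GenomicRanges::width(mergeIntervals(x, genome))))
}
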