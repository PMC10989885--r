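#' Read an allc-style per-cytosine methylation table
#'
#' Parses the methylpy "allc" dialect: a headerless TSV with columns
#' chromosome, position (1-based), strand (+/-), trinucleotide context,
#' methylated read count, total read count, and an optional trailing flag.
#' Plain or gzipped files are accepted. The trinucleotide is re-classified
#' into CG/CHG/CHH on read; trinucleotides containing N (or truncated at a
#' contig end) become context "undefined" and are ignored by every
#' statistic. When \code{genome} is supplied, each record is validated
#' against the reference (the base at the site must be C on + records and G
#' on - records) and unknown chromosomes are an error.
#'
#' @param path allc TSV (optionally .gz)
#' @param genome optional \code{DNAStringSet} for validation
#' @param controlContig unmethylated control contig name recorded in the
#'   returned object (defaults to the genome's, when supplied)
#' @return a \code{\link{Methylome}}
#' @export
readAllc <- function(path, genome = NULL, controlContig = NA_character_) {
  if (!file.exists(path)) stop("no such allc file: ", path)
  dt <- if (file.size(path) == 0) data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1L))
  if (is.null(controlContig) || is.na(controlContig)) {
    if (!is.null(genome)) {
      cc <- S4Vectors::metadata(genome)$controlContig
      if (!is.null(cc)) controlContig <- cc
    }
  }
  if (nrow(dt) == 0L) {
    warning("empty allc file: ", path)
    gr <- GenomicRanges::GRanges(
      subcontext = character(), context = character(),
      mc = integer(), cov = integer())
    return(Methylome(gr, controlContig))
  }
  if (!ncol(dt) %in% c(6L, 7L)) {
    stop("allc file must have 6 or 7 tab-separated columns, found ", ncol(dt))
  }
  data.table::setnames(dt, seq_len(6L),
                       c("chrom", "pos", "strand", "subcontext", "mc", "cov"))
  if (any(!dt$strand %in% c("+", "-"))) {
    stop("invalid strand at line(s): ",
         paste(utils::head(which(!dt$strand %in% c("+", "-")), 5),
               collapse = ", "))
  }
  bad <- which(dt$mc > dt$cov | dt$mc < 0L | dt$cov < 0L)
  if (length(bad)) {
    stop("mc > cov (or negative count) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    unk <- setdiff(unique(dt$chrom), names(genome))
    if (length(unk)) {
      stop("allc records on chromosome(s) absent from genome: ",
           paste(unk, collapse = ", "))
    }
    for (ch in unique(dt$chrom)) {
      rows <- which(dt$chrom == ch)
      L <- Biostrings::width(genome)[match(ch, names(genome))]
      if (any(dt$pos[rows] < 1L | dt$pos[rows] > L)) {
        stop("allc position outside chromosome ", ch)
      }
      base <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]][dt$pos[rows]]
      want <- ifelse(dt$strand[rows] == "+", "C", "G")
      if (any(base != want)) {
        stop("allc record does not sit on a cytosine of its strand (chrom ",
             ch, ", e.g. line ", rows[which(base != want)[1]], ")")
      }
    }
  }
  cl <- .classifyTriplet(dt$subcontext)
  cl$context[nchar(dt$subcontext) < 3L] <- "undefined"
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$pos, width = 1L),
    strand = dt$strand,
    subcontext = toupper(dt$subcontext), context = cl$context,
    mc = as.integer(dt$mc), cov = as.integer(dt$cov)
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- genomeSeqlengths(genome)
  }
  Methylome(sort(gr, ignore.strand = TRUE), controlContig)
}

#' Write a Methylome as an allc-style TSV
#'
#' @param meth a \code{\link{Methylome}}
#' @param path output TSV (".gz" suffix compresses)
#' @return \code{path}, invisibly
#' @export
writeAllc <- function(meth, path) {
  gr <- methSites(meth)
  m <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    context = m$subcontext, mc = m$mc, cov = m$cov, flag = 1L)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Estimate the bisulfite nonconversion rate from an unmethylated contig
#'
#' The chloroplast genome is unmethylated, so any methylated calls there are
#' failed bisulfite conversions: epsilon = sum(mc) / sum(cov) over all sites
#' of the control contig, all contexts.
#'
#' @param meth a \code{\link{Methylome}}
#' @param contig control contig name; defaults to the Methylome's
#' @return list with \code{epsilon}, \code{mcSum}, \code{covSum},
#'   \code{contig}
#' @export
estimateNonconversion <- function(meth, contig = controlContig(meth)) {
  if (is.na(contig)) stop("no control contig designated; supply `contig`")
  gr <- methSites(meth)
  sel <- as.character(GenomicRanges::seqnames(gr)) == contig
  m <- S4Vectors::mcols(gr)[sel, , drop = FALSE]
  covSum <- sum(as.numeric(m$cov))
  if (!any(sel) || covSum == 0) {
    stop("no covered sites on control contig '", contig,
         "'; supply epsilon manually")
  }
  mcSum <- sum(as.numeric(m$mc))
  list(epsilon = mcSum / covSum, mcSum = mcSum, covSum = covSum,
       contig = contig)
}

#' Call methylated sites against the nonconversion background
#'
#' For each covered cytosine, a one-sided binomial test of the methylated
#' read count against the nonconversion rate: p = P(X >= mc | n = cov,
#' p = epsilon). Benjamini-Hochberg correction is applied separately within
#' each context class (CG, CHG, CHH), whose site counts and effect sizes
#' differ by orders of magnitude; a site is called methylated when
#' q < alpha.
#'
#' @param meth a \code{\link{Methylome}}
#' @param epsilon nonconversion rate in [0,1] (see
#'   \code{\link{estimateNonconversion}})
#' @param alpha FDR threshold (default 0.05)
#' @param minCov minimum coverage for a site to be tested (default 1)
#' @return the Methylome with mcols \code{p}, \code{q}, \code{methylated}
#'   added (NA for untested sites)
#' @export
callSites <- function(meth, epsilon, alpha = 0.05, minCov = 1L) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single probability in [0,1]")
  }
  gr <- methSites(meth)
  m <- S4Vectors::mcols(gr)
  testable <- m$cov >= minCov & m$context %in% c("CG", "CHG", "CHH")
  p <- rep(NA_real_, length(gr))
  p[testable] <- stats::pbinom(m$mc[testable] - 1L, m$cov[testable],
                               epsilon, lower.tail = FALSE)
  q <- rep(NA_real_, length(gr))
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- testable & m$context == ctx
    if (any(sel)) q[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  S4Vectors::mcols(gr)$p <- p
  S4Vectors::mcols(gr)$q <- q
  S4Vectors::mcols(gr)$methylated <- !is.na(q) & q < alpha
  Methylome(gr, controlContig(meth))
}

## Site selection shared by the aggregate statistics: defined context,
## coverage floor, optional region restriction, control contig excluded.
.selectSites <- function(meth, regions = NULL, contexts = NULL, minCov = 1L,
                         excludeControl = TRUE) {
  gr <- methSites(meth)
  m <- S4Vectors::mcols(gr)
  keep <- m$cov >= minCov & m$context != "undefined"
  if (!is.null(contexts)) keep <- keep & m$context %in% contexts
  if (excludeControl && !is.na(controlContig(meth))) {
    keep <- keep & as.character(GenomicRanges::seqnames(gr)) !=
      controlContig(meth)
  }
  gr <- gr[keep]
  if (!is.null(regions)) {
    gr <- gr[IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)]
  }
  gr
}

.levelRow <- function(label, mc, cov, n, minCov) {
  mcs <- sum(as.numeric(mc)); covs <- sum(as.numeric(cov))
  data.frame(context = label, mc_sum = mcs, cov_sum = covs,
             level = if (covs > 0) mcs / covs else NA_real_,
             n_sites = n, min_cov = minCov, stringsAsFactors = FALSE)
}

#' Weighted DNA methylation level
#'
#' The coverage-weighted methylation level of a region set: total methylated
#' read count divided by total read count over all qualifying sites (defined
#' context, coverage >= \code{minCov}, inside \code{regions} when given).
#' Sites on the control contig are excluded. Reported per context, with an
#' optional pooled row over all requested contexts.
#'
#' @param meth a \code{\link{Methylome}}
#' @param regions optional \code{GRanges} restriction
#' @param contexts contexts to report (default CG, CHG, CHH)
#' @param minCov per-site minimum coverage (default 5, the aggregate-level
#'   convention; per-site level reporting conventionally uses 3)
#' @param pooled also report a single row pooling the requested contexts
#' @return \code{data.frame} with columns context, mc_sum, cov_sum, level
#'   (NA when no site qualifies), n_sites, min_cov
#' @export
weightedMethylation <- function(meth, regions = NULL,
                                contexts = c("CG", "CHG", "CHH"),
                                minCov = 5L, pooled = FALSE) {
  if (minCov < 1L) stop("minCov must be >= 1")
  gr <- .selectSites(meth, regions, contexts, minCov)
  m <- S4Vectors::mcols(gr)
  rows <- lapply(contexts, function(ctx) {
    sel <- m$context == ctx
    .levelRow(ctx, m$mc[sel], m$cov[sel], sum(sel), minCov)
  })
  out <- do.call(rbind, rows)
  if (pooled) {
    out <- rbind(out, .levelRow("all", m$mc, m$cov, length(gr), minCov))
  }
  out
}

#' Weighted methylation per genome window
#'
#' @param meth a \code{\link{Methylome}}
#' @param windows \code{GRanges} from \code{\link{tileWindows}}
#' @inheritParams weightedMethylation
#' @return \code{data.frame}: one row per (window, context) with window
#'   coordinates, the \code{partial} flag, counts and level
#' @export
windowedMethylation <- function(meth, windows,
                                contexts = c("CG", "CHG", "CHH"),
                                minCov = 5L) {
  gr <- .selectSites(meth, NULL, contexts, minCov, excludeControl = FALSE)
  hits <- GenomicRanges::findOverlaps(gr, windows, ignore.strand = TRUE)
  m <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    window = S4Vectors::subjectHits(hits),
    context = m$context[S4Vectors::queryHits(hits)],
    mc = as.numeric(m$mc[S4Vectors::queryHits(hits)]),
    cov = as.numeric(m$cov[S4Vectors::queryHits(hits)]))
  agg <- dt[, list(mc_sum = sum(mc), cov_sum = sum(cov), n_sites = .N),
            by = c("window", "context")]
  grid <- data.table::CJ(window = seq_along(windows), context = contexts)
  agg <- as.data.frame(agg[grid, on = c("window", "context")])
  agg[is.na(agg$mc_sum), c("mc_sum", "cov_sum", "n_sites")] <- 0
  partial <- S4Vectors::mcols(windows)$partial
  out <- data.frame(
    window = agg$window,
    chrom = as.character(GenomicRanges::seqnames(windows))[agg$window],
    start = GenomicRanges::start(windows)[agg$window],
    end = GenomicRanges::end(windows)[agg$window],
    partial = if (is.null(partial)) NA else partial[agg$window],
    context = agg$context, mc_sum = agg$mc_sum, cov_sum = agg$cov_sum,
    level = ifelse(agg$cov_sum > 0, agg$mc_sum / agg$cov_sum, NA_real_),
    n_sites = agg$n_sites, stringsAsFactors = FALSE)
  out[order(out$window, out$context), , drop = FALSE]
}

#' Weighted methylation by trinucleotide subcontext
#'
#' Reports a weighted level per trinucleotide subcontext, with CG merged
#' over its third base, plus the rollups used for pathway diagnosis:
#' CWG (CAG+CTG) and CCG within CHG; CWA and non-CWA within CHH; and the
#' three context totals.
#'
#' @inheritParams weightedMethylation
#' @return \code{data.frame} with columns label, kind
#'   ("subcontext"/"rollup"), mc_sum, cov_sum, level, n_sites
#' @export
subcontextSummary <- function(meth, minCov = 5L) {
  gr <- .selectSites(meth, NULL, c("CG", "CHG", "CHH"), minCov)
  m <- S4Vectors::mcols(gr)
  sub <- ifelse(m$context == "CG", "CG", m$subcontext)
  sub[grepl("N", sub)] <- NA_character_
  cl <- .classifyTriplet(ifelse(m$context == "CG", "CGA", m$subcontext))
  dt <- data.table::data.table(label = sub, context = m$context,
                               cwa = cl$cwa, symmetry = cl$symmetry,
                               mc = as.numeric(m$mc), cov = as.numeric(m$cov))
  dt <- dt[!is.na(dt$label), ]
  one <- function(sel, label, kind) {
    d <- dt[sel, ]
    data.frame(label = label, kind = kind,
               mc_sum = sum(d$mc), cov_sum = sum(d$cov),
               level = if (sum(d$cov) > 0) sum(d$mc) / sum(d$cov) else
                 NA_real_,
               n_sites = nrow(d), stringsAsFactors = FALSE)
  }
  subs <- sort(unique(dt$label))
  out <- do.call(rbind, lapply(subs, function(s)
    one(dt$label == s, s, "subcontext")))
  roll <- rbind(
    one(dt$symmetry == "CWG-dyad", "CWG", "rollup"),
    one(dt$symmetry == "CCG", "CCG", "rollup"),
    one(dt$context == "CHH" & dt$cwa, "CWA", "rollup"),
    one(dt$context == "CHH" & !dt$cwa, "CHH-nonCWA", "rollup"),
    one(dt$context == "CG", "CG", "rollup"),
    one(dt$context == "CHG", "CHG", "rollup"),
    one(dt$context == "CHH", "CHH", "rollup"))
  rbind(out, roll)
}

#' Per-strand methylation of symmetric dyads
#'
#' Pairs symmetric cytosines (CG dyads at offset 1; CWG dyads at offset 2)
#' and reports each strand's site-level methylation (mc/cov), keeping only
#' dyads where both strands meet the coverage floor. Used to assay
#' maintenance-methylation symmetry between Watson and Crick strands.
#'
#' @param meth a \code{\link{Methylome}}
#' @param minCov per-strand minimum coverage (default 3)
#' @param kinds dyad kinds to report ("CG", "CWG", and "CCG" when
#'   \code{includeCCG})
#' @param includeCCG also pair CCG sites with their opposite-strand cytosine
#' @return \code{data.frame}: chrom, watson_pos, crick_pos, kind, per-strand
#'   cov and level, and \code{delta} = watson_level - crick_level
#' @export
dyadLevels <- function(meth, minCov = 3L, kinds = c("CG", "CWG"),
                       includeCCG = FALSE) {
  gr <- methSites(meth)
  if (!is.na(controlContig(meth))) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) != controlContig(meth)]
  }
  pairs <- pairDyads(gr, includeCCG = includeCCG)
  pairs <- pairs[pairs$kind %in% kinds, , drop = FALSE]
  m <- S4Vectors::mcols(gr)
  wc <- m$cov[pairs$watson]; cc <- m$cov[pairs$crick]
  keep <- wc >= minCov & cc >= minCov
  pairs <- pairs[keep, , drop = FALSE]
  wc <- wc[keep]; cc <- cc[keep]
  wl <- m$mc[pairs$watson] / wc
  clv <- m$mc[pairs$crick] / cc
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[pairs$watson],
    watson_pos = GenomicRanges::start(gr)[pairs$watson],
    crick_pos = GenomicRanges::start(gr)[pairs$crick],
    kind = pairs$kind,
    watson_cov = wc, crick_cov = cc,
    watson_level = wl, crick_level = clv,
    delta = wl - clv, stringsAsFactors = FALSE)
}

#' Summarize dyad strand symmetry
#'
#' @param dyads output of \code{\link{dyadLevels}}
#' @return per-kind \code{data.frame}: n dyads, mean |watson - crick|,
#'   Pearson correlation of the strand levels
#' @export
summarizeDyads <- function(dyads) {
  sp <- split(dyads, dyads$kind)
  do.call(rbind, lapply(names(sp), function(k) {
    d <- sp[[k]]
    data.frame(kind = k, n = nrow(d),
               mean_abs_delta = mean(abs(d$delta)),
               correlation = if (nrow(d) > 2 &&
                                 stats::sd(d$watson_level) > 0 &&
                                 stats::sd(d$crick_level) > 0)
                 stats::cor(d$watson_level, d$crick_level) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Metaplot: pooled methylation over locus bodies and flanks
#'
#' Each locus body (start-to-stop for genes, first-to-last bp for
#' transposons) is divided into \code{nWindows} proportional windows; the
#' \code{flankBp} upstream and downstream flanks are divided into
#' \code{nWindows} fixed-width windows each (flankBp/nWindows bp). Window 1
#' is always the 5'-most upstream window: minus-strand loci are mirrored.
#' One pooled weighted level is computed per window across all loci (ratio
#' of summed counts, not a mean of per-locus ratios). When an exonic mask is
#' supplied, body windows count only positions inside it (the coding-exonic
#' restriction for genes); flank windows are unaffected. Windows running off
#' a chromosome end simply contribute the sites that exist. Loci shorter
#' than \code{nWindows} bp are skipped with a warning.
#'
#' @param meth a \code{\link{Methylome}}
#' @param loci stranded \code{GRanges} of genes or transposons
#' @param flankBp flank length in bp (default 1000)
#' @param nWindows windows per segment (default 20; 3*nWindows total)
#' @param exonic optional \code{GRanges} mask restricting body windows
#' @param contexts contexts to profile
#' @param minCov per-site minimum coverage (default 5)
#' @param pooled add rows pooling all requested contexts per window
#' @return \code{data.frame}: window (1..3*nWindows), segment
#'   (upstream/body/downstream), context, mc_sum, cov_sum, level, n_sites
#' @export
metaplotProfile <- function(meth, loci, flankBp = 1000L, nWindows = 20L,
                            exonic = NULL, contexts = c("CG", "CHG", "CHH"),
                            minCov = 5L, pooled = FALSE) {
  stopifnot(flankBp >= nWindows, nWindows >= 1L)
  gr <- .selectSites(meth, NULL, contexts, minCov)
  short <- GenomicRanges::width(loci) < nWindows
  if (any(short)) {
    warning(sum(short), " locus/loci shorter than ", nWindows,
            " bp skipped")
    loci <- loci[!short]
  }
  if (!length(loci)) stop("no usable loci")
  ls <- GenomicRanges::start(loci); le <- GenomicRanges::end(loci)
  lstr <- as.character(GenomicRanges::strand(loci))
  lstr[lstr == "*"] <- "+"
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(loci),
    IRanges::IRanges(pmax(ls - flankBp, 1L), le + flankBp))
  suppressWarnings(hits <- GenomicRanges::findOverlaps(
    gr, ext, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(gr)[qi]
  s <- ls[si]; e <- le[si]; st <- lstr[si]; L <- e - s + 1
  inExon <- if (is.null(exonic)) TRUE else
    IRanges::overlapsAny(gr, GenomicRanges::reduce(exonic,
                                                   ignore.strand = TRUE),
                         ignore.strand = TRUE)[qi]
  nW <- as.integer(nWindows)
  win <- rep(NA_integer_, length(qi))
  body <- pos >= s & pos <= e
  rel <- ifelse(st == "+", pos - s, e - pos)
  win[body] <- nW + pmin(floor(rel[body] * nW / L[body]), nW - 1L) + 1L
  if (!is.null(exonic)) win[body & !inExon] <- NA_integer_
  up <- (st == "+" & pos < s & pos >= s - flankBp) |
    (st == "-" & pos > e & pos <= e + flankBp)
  relu <- ifelse(st == "+", pos - (s - flankBp), e + flankBp - pos)
  win[up] <- pmin(floor(relu[up] * nW / flankBp), nW - 1L) + 1L
  down <- (st == "+" & pos > e & pos <= e + flankBp) |
    (st == "-" & pos < s & pos >= s - flankBp)
  reld <- ifelse(st == "+", pos - e - 1, s - 1 - pos)
  win[down] <- 2L * nW + pmin(floor(reld[down] * nW / flankBp), nW - 1L) + 1L
  m <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    window = win, context = m$context[qi],
    mc = as.numeric(m$mc[qi]), cov = as.numeric(m$cov[qi]))
  dt <- dt[!is.na(dt$window), ]
  if (pooled) {
    dt <- rbind(dt, data.table::data.table(
      window = dt$window, context = "all", mc = dt$mc, cov = dt$cov))
  }
  agg <- dt[, list(mc_sum = sum(mc), cov_sum = sum(cov), n_sites = .N),
            by = c("window", "context")]
  ctxs <- if (pooled) c(contexts, "all") else contexts
  grid <- data.table::CJ(window = seq_len(3L * nW), context = ctxs)
  agg <- as.data.frame(agg[grid, on = c("window", "context")])
  agg[is.na(agg$mc_sum), c("mc_sum", "cov_sum", "n_sites")] <- 0
  seg <- rep(c("upstream", "body", "downstream"), each = nW)
  data.frame(window = agg$window, segment = seg[agg$window],
             context = agg$context, mc_sum = agg$mc_sum,
             cov_sum = agg$cov_sum,
             level = ifelse(agg$cov_sum > 0, agg$mc_sum / agg$cov_sum,
                            NA_real_),
             n_sites = agg$n_sites, stringsAsFactors = FALSE)
}
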