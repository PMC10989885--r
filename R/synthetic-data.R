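#' Configuration for the synthetic methylome generator
#'
#' Defaults emulate the structure of a compact duckweed-like genome at
#' miniature scale: a few short chromosomes instead of 20 long ones, an
#' unmethylated chloroplast contig, ~10% of CG sites methylated as
#' all-or-nothing symmetric dyads, weak CWG-restricted CHG methylation,
#' absent CHH methylation, a small pericentromeric H3K9me2 domain per
#' chromosome plus scattered peaks to ~15% occupancy, and a 21-nt-dominant
#' small RNA pool with 24-nt reads nearly absent.
#'
#' @param seed integer seed; fixes every downstream draw
#' @param nChroms,chromLenBp nuclear chromosome count and length
#' @param gcFraction genome GC content
#' @param nGenes,exonsPerGene,geneLenRange gene complement
#' @param nLtr,ltrLenRange LTR retrotransposon annotations
#' @param gbmGeneFraction fraction of genes given gene-body CG methylation
#' @param pMCG,pMCHG,pMCHH per-dyad/site methylation probabilities
#'   (methylated background sites are all-or-nothing, level 1)
#' @param gbmBetaMean,betaConcentration Beta distribution of gbM exonic CG
#'   site levels
#' @param chhBetaMean mean level of a methylated CHH site (rarely used;
#'   pMCHH defaults to 0)
#' @param uniformLevel when set, every nuclear site gets this true level
#'   (all contexts) - a flat-methylome mode for calibration
#' @param symmetricMaintenance share true levels across dyad partners (CG
#'   and CWG); when FALSE strands are independent
#' @param coverageMean,coverageModel,dispersion per-site read depth:
#'   "poisson" or "nbinom" (negative binomial with size = dispersion)
#' @param epsilon bisulfite nonconversion rate (false-methylated signal on
#'   unmethylated molecules)
#' @param peakDomainBp,targetOccupancy,scatterPeakLenRange H3K9me2 peak
#'   geometry
#' @param ltrInDomainFraction fraction of LTRs placed inside the
#'   pericentromeric domain
#' @param nSrna,srnaLengthWeights small RNA read count and length mix
#' @param includeChloroplast,chloroplastLenBp unmethylated control contig
#' @return a validated \code{SynthConfig} list
#' @export
synthConfig <- function(seed = 1L,
                        nChroms = 4L, chromLenBp = 50000L,
                        gcFraction = 0.43,
                        nGenes = 96L, exonsPerGene = 3L,
                        geneLenRange = c(800L, 2000L),
                        nLtr = 40L, ltrLenRange = c(500L, 2000L),
                        gbmGeneFraction = 0.025,
                        pMCG = 0.10, pMCHG = 0.03, pMCHH = 0,
                        gbmBetaMean = 0.85, betaConcentration = 20,
                        chhBetaMean = 0.3,
                        uniformLevel = NA_real_,
                        symmetricMaintenance = TRUE,
                        coverageMean = 20, coverageModel = "poisson",
                        dispersion = 5,
                        epsilon = 0.005,
                        peakDomainBp = 4000L, targetOccupancy = 0.15,
                        scatterPeakLenRange = c(200L, 600L),
                        ltrInDomainFraction = 0.5,
                        nSrna = 10000L,
                        srnaLengthWeights = c("20" = 0.07, "21" = 0.70,
                                              "22" = 0.10, "23" = 0.05,
                                              "24" = 0.05, "25" = 0.03),
                        includeChloroplast = TRUE,
                        chloroplastLenBp = 12000L) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLenBp = as.integer(chromLenBp), gcFraction = gcFraction,
              nGenes = as.integer(nGenes),
              exonsPerGene = as.integer(exonsPerGene),
              geneLenRange = as.integer(geneLenRange),
              nLtr = as.integer(nLtr), ltrLenRange = as.integer(ltrLenRange),
              gbmGeneFraction = gbmGeneFraction,
              pMCG = pMCG, pMCHG = pMCHG, pMCHH = pMCHH,
              gbmBetaMean = gbmBetaMean,
              betaConcentration = betaConcentration,
              chhBetaMean = chhBetaMean,
              uniformLevel = uniformLevel,
              symmetricMaintenance = isTRUE(symmetricMaintenance),
              coverageMean = coverageMean,
              coverageModel = match.arg(coverageModel,
                                        c("poisson", "nbinom")),
              dispersion = dispersion, epsilon = epsilon,
              peakDomainBp = as.integer(peakDomainBp),
              targetOccupancy = targetOccupancy,
              scatterPeakLenRange = as.integer(scatterPeakLenRange),
              ltrInDomainFraction = ltrInDomainFraction,
              nSrna = as.integer(nSrna),
              srnaLengthWeights = srnaLengthWeights,
              includeChloroplast = isTRUE(includeChloroplast),
              chloroplastLenBp = as.integer(chloroplastLenBp))
  probs <- c(cfg$gcFraction, cfg$gbmGeneFraction, cfg$pMCG, cfg$pMCHG,
             cfg$pMCHH, cfg$gbmBetaMean, cfg$chhBetaMean, cfg$epsilon,
             cfg$targetOccupancy, cfg$ltrInDomainFraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0,1]")
  }
  if (!is.na(cfg$uniformLevel) &&
      (cfg$uniformLevel < 0 || cfg$uniformLevel > 1)) {
    stop("uniformLevel must lie in [0,1]")
  }
  if (any(c(cfg$nChroms, cfg$chromLenBp, cfg$coverageMean) <= 0)) {
    stop("counts and lengths must be positive")
  }
  if (abs(sum(cfg$srnaLengthWeights) - 1) > 1e-6) {
    stop("srnaLengthWeights must sum to 1")
  }
  if (is.null(names(cfg$srnaLengthWeights))) {
    stop("srnaLengthWeights must be named by read length")
  }
  if (cfg$peakDomainBp >= cfg$chromLenBp) {
    stop("peak domain longer than chromosome")
  }
  class(cfg) <- c("SynthConfig", "list")
  cfg
}

.randomSeq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Partition a gene span into alternating exon/intron widths (>= 80 bp
## each). Segment proportions are Dirichlet-distributed so exon/intron
## boundaries vary between genes, as in real annotations.
.geneStructure <- function(len, nExons) {
  nSeg <- 2L * nExons - 1L
  minw <- 80L
  if (len < nSeg * minw) nExons <- max(1L, (len %/% minw + 1L) %/% 2L)
  nSeg <- 2L * nExons - 1L
  extra <- len - nSeg * minw
  add <- if (extra > 0 && nSeg > 1) {
    stats::rmultinom(1, extra, stats::rgamma(nSeg, 1))[, 1]
  } else if (nSeg == 1) extra else rep(0L, nSeg)
  widths <- minw + add
  isExon <- seq_len(nSeg) %% 2L == 1L
  list(widths = as.integer(widths), isExon = isExon)
}

#' Generate the synthetic genome and annotations
#'
#' Random nuclear chromosomes at the configured GC content with
#' non-overlapping genes placed in the chromosome arms, a reserved
#' pericentromeric domain per chromosome, LTR retrotransposon annotations
#' (a configurable fraction inside the domain; element intervals may nest,
#' as real TE annotations do), and an optional unmethylated chloroplast
#' contig ("chrC").
#'
#' @param config a \code{\link{synthConfig}}
#' @return list: \code{genome} (DNAStringSet), \code{genes}, \code{exons},
#'   \code{cds}, \code{ltr}, \code{domains} (GRanges)
#' @export
generateGenome <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChroms))
  seqs <- vapply(chroms, function(ch)
    .randomSeq(config$chromLenBp, config$gcFraction), character(1))
  L <- config$chromLenBp
  dStart <- (L - config$peakDomainBp) %/% 2L + 1L
  domains <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(dStart, width = config$peakDomainBp))
  ## genes: sequential placement in the arms, never inside the domain;
  ## genes that no longer fit on one chromosome spill onto the next
  genes <- list(); exons <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- 1L + sample(50:200, 1)
    while (gi < config$nGenes) {
      glen <- sample(config$geneLenRange[1]:config$geneLenRange[2], 1)
      if (cursor <= dStart + config$peakDomainBp &&
          cursor + glen - 1L >= dStart) {
        cursor <- dStart + config$peakDomainBp + sample(50:200, 1)
      }
      if (cursor + glen - 1L > L - 100L) break
      gi <- gi + 1L
      id <- sprintf("gene%04d", gi)
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- GenomicRanges::GRanges(
        factor(chroms[ci], levels = chroms),
        IRanges::IRanges(cursor, width = glen), strand,
        gene_id = id)
      st <- .geneStructure(glen, config$exonsPerGene)
      segStart <- cursor + c(0L, cumsum(st$widths))[seq_along(st$widths)]
      ex <- which(st$isExon)
      exons[[gi]] <- GenomicRanges::GRanges(
        factor(chroms[ci], levels = chroms),
        IRanges::IRanges(segStart[ex], width = st$widths[ex]),
        strand, gene_id = id, exon_rank = seq_along(ex))
      cursor <- cursor + glen + sample(80:400, 1)
    }
  }
  if (gi < config$nGenes) {
    stop("could only place ", gi, " of ", config$nGenes,
         " genes; reduce nGenes or geneLenRange, or increase chromLenBp")
  }
  genesGr <- do.call(c, genes)
  exonsGr <- do.call(c, exons)
  ## LTR annotations: a fraction inside the pericentromeric domain
  nIn <- round(config$nLtr * config$ltrInDomainFraction)
  ltr <- vector("list", config$nLtr)
  for (i in seq_len(config$nLtr)) {
    ci <- sample(config$nChroms, 1)
    tlen <- sample(config$ltrLenRange[1]:config$ltrLenRange[2], 1)
    if (i <= nIn) {
      lo <- dStart; hi <- dStart + config$peakDomainBp - tlen
      if (hi < lo) { hi <- lo }
      s <- sample(lo:hi, 1)
    } else {
      repeat {
        s <- sample(seq_len(L - tlen), 1)
        if (s + tlen - 1L < dStart || s > dStart + config$peakDomainBp - 1L)
          break
      }
    }
    ltr[[i]] <- GenomicRanges::GRanges(
      factor(chroms[ci], levels = chroms),
      IRanges::IRanges(s, width = tlen), "+",
      ltr_id = sprintf("LTR%04d", i), in_domain = i <= nIn)
  }
  ltrGr <- sort(do.call(c, ltr), ignore.strand = TRUE)
  if (config$includeChloroplast) {
    seqs <- c(seqs, chrC = .randomSeq(config$chloroplastLenBp,
                                      config$gcFraction))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(genome) <- S4Vectors::DataFrame(
    organelle = names(genome) == "chrC")
  S4Vectors::metadata(genome) <- list(
    controlContig = if (config$includeChloroplast) "chrC" else NA_character_)
  sl <- genomeSeqlengths(genome)
  fix <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  }
  list(genome = genome, genes = fix(genesGr), exons = fix(exonsGr),
       cds = fix(exonsGr), ltr = fix(ltrGr), domains = fix(domains))
}

#' Generate the synthetic methylome with known truth
#'
#' Assigns every cytosine site a true methylation level and simulates read
#' counts. Background CG and (when symmetric maintenance is on) CWG sites
#' are methylated as all-or-nothing epialleles: a dyad is methylated with
#' probability \code{pMCG}/\code{pMCHG} and both strands then carry level 1,
#' the fully maintained state. Exonic CG sites of the designated gbM genes
#' draw levels from Beta(gbmBetaMean, betaConcentration), shared across the
#' dyad. CHH sites are methylated independently with probability
#' \code{pMCHH} (absent by default). Chloroplast sites have true level 0
#' exactly. Observed counts are mc ~ Binomial(cov, level + (1-level) *
#' epsilon): nonconversion contributes false-methylated signal on
#' unmethylated molecules only.
#'
#' @param genomeObj output of \code{\link{generateGenome}}
#' @param config the same \code{\link{synthConfig}}
#' @return list: \code{meth} (a \code{\link{Methylome}} of sites with
#'   coverage >= 1), \code{truth} (data.frame per enumerated site: true
#'   level, region label, simulated cov), \code{gbmGenes} (ids),
#'   \code{epsilon}
#' @export
generateMethylome <- function(genomeObj, config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed + 1L)
  genome <- genomeObj$genome
  sites <- cytosineSites(genome)
  m <- S4Vectors::mcols(sites)
  n <- length(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  organelle <- chrom %in% names(genome)[S4Vectors::mcols(genome)$organelle]
  defined <- m$context != "undefined"
  level <- rep(0, n)
  nGbm <- round(config$gbmGeneFraction * config$nGenes)
  gbmGenes <- sort(sample(S4Vectors::mcols(genomeObj$genes)$gene_id, nGbm))
  gbmExons <- genomeObj$exons[
    S4Vectors::mcols(genomeObj$exons)$gene_id %in% gbmGenes]
  inGbmExon <- IRanges::overlapsAny(sites, gbmExons, ignore.strand = TRUE)
  region <- ifelse(organelle, "chloroplast",
                   ifelse(inGbmExon, "gbM_exon", "background"))
  if (!is.na(config$uniformLevel)) {
    level[defined & !organelle] <- config$uniformLevel
  } else {
    dy <- pairDyads(sites)
    inDyad <- rep(FALSE, n)
    inDyad[dy$watson] <- TRUE; inDyad[dy$crick] <- TRUE
    eligible <- defined & !organelle
    a <- config$gbmBetaMean * config$betaConcentration
    b <- (1 - config$gbmBetaMean) * config$betaConcentration
    if (config$symmetricMaintenance) {
      ## CG dyads: shared all-or-nothing state
      cg <- dy[dy$kind == "CG", , drop = FALSE]
      cg <- cg[!organelle[cg$watson], , drop = FALSE]
      on <- stats::runif(nrow(cg)) < config$pMCG
      level[cg$watson[on]] <- 1; level[cg$crick[on]] <- 1
      ## gbM exonic CG dyads: shared Beta level (overrides background)
      gb <- inGbmExon[cg$watson] | inGbmExon[cg$crick]
      if (any(gb)) {
        bl <- stats::rbeta(sum(gb), a, b)
        level[cg$watson[gb]] <- bl; level[cg$crick[gb]] <- bl
      }
      ## unpaired CG sites (contig ends): independent
      soloCG <- which(eligible & m$context == "CG" & !inDyad)
      level[soloCG] <- ifelse(stats::runif(length(soloCG)) < config$pMCG,
                              1, 0)
      gbSolo <- intersect(soloCG, which(inGbmExon))
      level[gbSolo] <- stats::rbeta(length(gbSolo), a, b)
      ## CWG dyads: shared; CCG stays unmethylated
      cwg <- dy[dy$kind == "CWG", , drop = FALSE]
      cwg <- cwg[!organelle[cwg$watson], , drop = FALSE]
      on <- stats::runif(nrow(cwg)) < config$pMCHG
      level[cwg$watson[on]] <- 1; level[cwg$crick[on]] <- 1
    } else {
      cgAll <- which(eligible & m$context == "CG")
      level[cgAll] <- ifelse(stats::runif(length(cgAll)) < config$pMCG,
                             1, 0)
      gbAll <- intersect(cgAll, which(inGbmExon))
      level[gbAll] <- stats::rbeta(length(gbAll), a, b)
      chg <- which(eligible & m$context == "CHG")
      level[chg] <- ifelse(stats::runif(length(chg)) < config$pMCHG, 1, 0)
    }
    if (config$pMCHH > 0) {
      chh <- which(eligible & m$context == "CHH")
      on <- stats::runif(length(chh)) < config$pMCHH
      ca <- config$chhBetaMean * config$betaConcentration
      cb <- (1 - config$chhBetaMean) * config$betaConcentration
      level[chh[on]] <- stats::rbeta(sum(on), ca, cb)
    }
  }
  level[!defined] <- 0
  cov <- if (config$coverageModel == "poisson") {
    stats::rpois(n, config$coverageMean)
  } else {
    stats::rnbinom(n, mu = config$coverageMean, size = config$dispersion)
  }
  pObs <- level + (1 - level) * config$epsilon
  mc <- stats::rbinom(n, cov, pObs)
  truth <- data.frame(
    chrom = chrom, pos = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    context = m$context, subcontext = m$subcontext,
    true_level = level, region = region, cov = cov,
    stringsAsFactors = FALSE)
  emit <- cov >= 1L
  gr <- sites[emit]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    subcontext = m$subcontext[emit], context = m$context[emit],
    mc = mc[emit], cov = cov[emit])
  meth <- Methylome(gr, if (config$includeChloroplast) "chrC" else
    NA_character_)
  list(meth = meth, truth = truth, gbmGenes = gbmGenes,
       epsilon = config$epsilon)
}

#' Expected observed weighted levels implied by the generator truth
#'
#' The law-of-large-numbers target for recovery checks: per context, the
#' coverage-weighted mean of level + (1-level) * epsilon over emitted
#' nuclear sites.
#'
#' @param truth truth table from \code{\link{generateMethylome}}
#' @param epsilon the configured nonconversion rate
#' @return named numeric vector (CG, CHG, CHH, all)
#' @export
truthExpectedLevels <- function(truth, epsilon) {
  t2 <- truth[truth$cov >= 1 & truth$region != "chloroplast" &
                truth$context != "undefined", , drop = FALSE]
  p <- t2$true_level + (1 - t2$true_level) * epsilon
  one <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(t2$cov[sel] * p[sel]) / sum(t2$cov[sel])
  }
  c(CG = one(t2$context == "CG"), CHG = one(t2$context == "CHG"),
    CHH = one(t2$context == "CHH"), all = one(rep(TRUE, nrow(t2))))
}

#' Generate the synthetic H3K9me2 peak set
#'
#' One contiguous pericentromeric domain per chromosome plus short peaks
#' scattered through the arms until the merged set reaches the target
#' genome occupancy.
#'
#' @inheritParams generateMethylome
#' @return \code{GRanges} of peaks; attribute \code{occupancy} holds the
#'   realized merged fraction
#' @export
generatePeaks <- function(genomeObj, config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed + 2L)
  genome <- genomeObj$genome
  G <- sum(as.numeric(Biostrings::width(genome)))
  peaks <- genomeObj$domains
  nuclear <- names(genome)[!S4Vectors::mcols(genome)$organelle]
  L <- config$chromLenBp
  dStart <- GenomicRanges::start(genomeObj$domains)[1]
  dEnd <- GenomicRanges::end(genomeObj$domains)[1]
  guard <- 0L
  while (coveredBp(peaks) / G < config$targetOccupancy && guard < 10000L) {
    guard <- guard + 1L
    plen <- sample(config$scatterPeakLenRange[1]:
                     config$scatterPeakLenRange[2], 1)
    ## trim the final peak so the merged set lands on the target
    deficit <- ceiling(config$targetOccupancy * G - coveredBp(peaks))
    plen <- max(1L, min(plen, as.integer(deficit)))
    ch <- sample(nuclear, 1)
    repeat {
      s <- sample(seq_len(L - plen), 1)
      if (s + plen - 1L < dStart || s > dEnd) break
    }
    peaks <- c(peaks, GenomicRanges::GRanges(
      factor(ch, levels = GenomeInfoDb::seqlevels(peaks)),
      IRanges::IRanges(s, width = plen)))
  }
  occ <- coveredBp(peaks) / G
  peaks <- sort(peaks, ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(peaks) <- names(genome)
  GenomeInfoDb::seqlengths(peaks) <- genomeSeqlengths(genome)
  attr(peaks, "occupancy") <- occ
  peaks
}

#' Generate synthetic small RNA reads
#'
#' Reads are drawn from random nuclear genome positions with lengths
#' sampled from the configured weights; half are reverse-complemented.
#'
#' @inheritParams generateMethylome
#' @return named \code{DNAStringSet} of reads
#' @export
generateSrna <- function(genomeObj, config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed + 3L)
  if (config$nSrna == 0L) return(Biostrings::DNAStringSet())
  genome <- genomeObj$genome
  nuclear <- which(!S4Vectors::mcols(genome)$organelle)
  lens <- as.integer(sample(names(config$srnaLengthWeights), config$nSrna,
                            replace = TRUE,
                            prob = config$srnaLengthWeights))
  w <- Biostrings::width(genome)[nuclear]
  ci <- sample(nuclear, config$nSrna, replace = TRUE, prob = w)
  starts <- floor(stats::runif(config$nSrna) *
                    (Biostrings::width(genome)[ci] - lens)) + 1L
  chars <- as.character(genome)
  reads <- substring(chars[ci], starts, starts + lens - 1L)
  flip <- stats::runif(config$nSrna) < 0.5
  out <- Biostrings::DNAStringSet(reads)
  out[flip] <- Biostrings::reverseComplement(out[flip])
  names(out) <- sprintf("read%06d", seq_len(config$nSrna))
  out
}

#' Write small RNA reads as FASTQ
#'
#' @param reads \code{DNAStringSet}
#' @param path output FASTQ (".gz" compresses)
#' @return \code{path}, invisibly
#' @export
writeSrnaFastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

## GFF3 writer for the synthetic annotation (gene/exon/CDS with Parent links)
.writeGff3 <- function(genes, exons, path) {
  g <- genes
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    type = "gene", ID = S4Vectors::mcols(genes)$gene_id)
  mk <- function(type, suffix) {
    e <- exons
    S4Vectors::mcols(e) <- S4Vectors::DataFrame(
      type = type,
      ID = paste0(S4Vectors::mcols(exons)$gene_id, suffix,
                  S4Vectors::mcols(exons)$exon_rank),
      Parent = S4Vectors::mcols(exons)$gene_id,
      phase = if (type == "CDS") 0L else NA_integer_)
    e
  }
  out <- c(g, mk("exon", ".exon"), mk("CDS", ".cds"))
  out <- sort(out, ignore.strand = TRUE)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation GFF3
#'
#' Extracts gene, exon and CDS features with Parent linkage from a GFF3
#' file (1-based closed coordinates, converted natively).
#'
#' @param path GFF3 file
#' @return list: \code{genes} (GRanges with \code{gene_id}), \code{exons},
#'   \code{cds} (GRanges with \code{gene_id}), \code{cdsByGene}
#'   (named \code{GRangesList})
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gff)
  type <- as.character(m$type)
  genes <- gff[type == "gene"]
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = m$ID[type == "gene"])
  getKids <- function(what) {
    kids <- gff[type == what]
    par <- as.character(S4Vectors::unstrsplit(
      S4Vectors::mcols(kids)$Parent, ","))
    S4Vectors::mcols(kids) <- S4Vectors::DataFrame(gene_id = par)
    kids
  }
  exons <- getKids("exon")
  cds <- getKids("CDS")
  cdsByGene <- GenomicRanges::split(cds, S4Vectors::mcols(cds)$gene_id)
  list(genes = genes, exons = exons, cds = cds,
       cdsByGene = cdsByGene)
}

#' Generate and write the complete synthetic dataset
#'
#' Runs the genome, methylome, peak and small RNA generators under one seed
#' and writes every output in its standard text format: genome.fa,
#' genes.gff3, ltr.bed, peaks.bed, allc.tsv, truth.tsv, srna.fastq and
#' config.json.
#'
#' @param config a \code{\link{synthConfig}}
#' @param outDir output directory (created if needed)
#' @return (invisibly) list of the in-memory objects plus \code{paths}
#' @export
simulateDataset <- function(config, outDir) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateGenome(config)
  methOut <- generateMethylome(gen, config)
  peaks <- generatePeaks(gen, config)
  srna <- generateSrna(gen, config)
  p <- function(f) file.path(outDir, f)
  Biostrings::writeXStringSet(gen$genome, p("genome.fa"))
  .writeGff3(gen$genes, gen$exons, p("genes.gff3"))
  ltrBed <- gen$ltr
  names(ltrBed) <- S4Vectors::mcols(ltrBed)$ltr_id
  rtracklayer::export(ltrBed, p("ltr.bed"), format = "bed")
  rtracklayer::export(peaks, p("peaks.bed"), format = "bed")
  writeAllc(methOut$meth, p("allc.tsv"))
  data.table::fwrite(methOut$truth, p("truth.tsv"), sep = "\t")
  writeSrnaFastq(srna, p("srna.fastq"))
  cfgOut <- config
  class(cfgOut) <- "list"
  jsonlite::write_json(cfgOut, p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(config = config, genome = gen, meth = methOut$meth,
                 truth = methOut$truth, gbmGenes = methOut$gbmGenes,
                 peaks = peaks, srna = srna,
                 paths = list(
                   fasta = p("genome.fa"), gff = p("genes.gff3"),
                   ltr = p("ltr.bed"), peaks = p("peaks.bed"),
                   allc = p("allc.tsv"), truth = p("truth.tsv"),
                   srna = p("srna.fastq"), config = p("config.json"))))
}
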