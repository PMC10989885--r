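#' Pipeline configuration
#'
#' Input paths and the analysis thresholds used across the stages. All
#' analysis stages are deterministic; the only randomness in the package
#' lives in the synthetic-data generator.
#'
#' @param allc allc-style per-cytosine TSV
#' @param fasta genome FASTA
#' @param gff gene annotation GFF3 (gene/exon/CDS)
#' @param ltrBed LTR retrotransposon annotations (BED), optional
#' @param peaksBed H3K9me2 peak intervals (BED), optional
#' @param srnaReads trimmed small RNA reads (FASTA/FASTQ), optional
#' @param controlContig unmethylated control contig name (for nonconversion)
#' @param minCovAggregate per-site coverage floor for weighted levels
#'   (default 5)
#' @param minCovSite coverage floor for per-site levels, site calls and
#'   dyads (default 3)
#' @param alpha FDR threshold for site and feature calls (default 0.05)
#' @param windowBp genome window width (default 50,000)
#' @param flankBp,nWindows metaplot geometry (defaults 1,000 and 20)
#' @param basis feature-enrichment counting basis ("reads" or "sites")
#' @param srnaRange small RNA size range profiled (default 20-25 nt)
#' @param epsilon override the nonconversion rate instead of estimating it
#' @return validated config list
#' @export
pipelineConfig <- function(allc, fasta, gff, ltrBed = NULL, peaksBed = NULL,
                           srnaReads = NULL, controlContig = NA_character_,
                           minCovAggregate = 5L, minCovSite = 3L,
                           alpha = 0.05, windowBp = 50000L,
                           flankBp = 1000L, nWindows = 20L,
                           basis = c("reads", "sites"),
                           srnaRange = c(20L, 25L),
                           epsilon = NA_real_) {
  cfg <- list(allc = allc, fasta = fasta, gff = gff, ltrBed = ltrBed,
              peaksBed = peaksBed, srnaReads = srnaReads,
              controlContig = controlContig,
              minCovAggregate = as.integer(minCovAggregate),
              minCovSite = as.integer(minCovSite), alpha = alpha,
              windowBp = as.integer(windowBp),
              flankBp = as.integer(flankBp),
              nWindows = as.integer(nWindows),
              basis = match.arg(basis),
              srnaRange = as.integer(srnaRange), epsilon = epsilon)
  if (any(c(cfg$minCovAggregate, cfg$minCovSite, cfg$windowBp, cfg$flankBp,
            cfg$nWindows) < 1L)) {
    stop("thresholds must be positive")
  }
  for (f in c("allc", "fasta", "gff")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("missing required input --", f, ": ",
           if (is.null(cfg[[f]])) "(not set)" else cfg[[f]])
    }
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Run the full methylome / chromatin / small RNA analysis
#'
#' Executes the stages in order - context enumeration, nonconversion
#' estimation, site calls, global/window/subcontext weighted levels, dyad
#' symmetry, gene metaplot, per-gene and per-LTR enrichment calls, peak
#' occupancy and overlap enrichment, and the small RNA size profile -
#' writing one TSV per stage plus a machine-readable \code{summary.json}
#' to \code{outDir} when given.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir optional output directory for TSVs and summary.json
#' @return (invisibly) a list with the \code{summary} (what summary.json
#'   holds) and the per-stage tables
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  genome <- readGenome(config$fasta, config$controlContig)
  meth <- readAllc(config$allc, genome,
                   controlContig = config$controlContig)
  eps <- if (!is.na(config$epsilon)) {
    list(epsilon = config$epsilon, mcSum = NA_real_, covSum = NA_real_,
         contig = NA_character_)
  } else {
    estimateNonconversion(meth)
  }
  meth <- callSites(meth, eps$epsilon, alpha = config$alpha,
                    minCov = config$minCovSite)
  m <- S4Vectors::mcols(methSites(meth))
  nuclear <- is.na(controlContig(meth)) |
    as.character(GenomicRanges::seqnames(methSites(meth))) !=
      controlContig(meth)
  siteFractions <- vapply(c("CG", "CHG", "CHH"), function(ctx) {
    sel <- nuclear & m$context == ctx & !is.na(m$q)
    if (!any(sel)) return(NA_real_)
    mean(m$methylated[sel])
  }, numeric(1))
  global <- weightedMethylation(meth, minCov = config$minCovAggregate)
  windows <- tileWindows(genome, config$windowBp)
  winMeth <- windowedMethylation(meth, windows,
                                 minCov = config$minCovAggregate)
  subctx <- subcontextSummary(meth, minCov = config$minCovAggregate)
  dyads <- dyadLevels(meth, minCov = config$minCovSite)
  dyadSummary <- summarizeDyads(dyads)
  ann <- readGeneAnnotation(config$gff)
  meta <- metaplotProfile(meth, ann$genes, flankBp = config$flankBp,
                          nWindows = config$nWindows, exonic = ann$cds,
                          minCov = config$minCovAggregate)
  gbm <- callFeatureEnrichment(meth, ann$cdsByGene, basis = config$basis,
                               alpha = config$alpha,
                               minCovSite = config$minCovSite)
  gbmGenes <- gbm$feature_id[gbm$class == "gbM"]
  out <- list(
    config = config,
    epsilon = eps, siteCalls = m, global = global, windows = winMeth,
    subcontexts = subctx, dyads = dyads, dyadSummary = dyadSummary,
    metaplot = meta, gbm = gbm)
  summary <- list(
    n_sites = length(meth),
    nonconversion_epsilon = eps$epsilon,
    weighted_level = stats::setNames(as.list(global$level), global$context),
    site_methylated_fraction = as.list(siteFractions),
    dyad_mean_abs_delta = stats::setNames(
      as.list(dyadSummary$mean_abs_delta), dyadSummary$kind),
    gbm = list(n_genes_tested = sum(gbm$class != "insufficient-data"),
               n_gbm = length(gbmGenes),
               n_chg_chh_enriched = sum(gbm$class == "CHG/CHH-enriched"),
               basis = config$basis,
               gbm_genes = gbmGenes))
  ltr <- NULL
  if (!is.null(config$ltrBed)) {
    ltr <- rtracklayer::import(config$ltrBed, format = "bed")
    ltrByFeature <- GenomicRanges::split(
      ltr, if (!is.null(ltr$name)) ltr$name else
        sprintf("LTR%04d", seq_along(ltr)))
    ltrCalls <- callFeatureEnrichment(meth, ltrByFeature,
                                      basis = config$basis,
                                      alpha = config$alpha,
                                      minCovSite = config$minCovSite)
    nChh <- sum(ltrCalls$enriched_CHH, na.rm = TRUE)
    out$ltrCalls <- ltrCalls
    summary$ltr <- list(
      n_total = length(ltr), n_chh_enriched = nChh,
      chh_enriched_fraction = enrichedFraction(nChh, length(ltr), 3L))
  }
  if (!is.null(config$peaksBed)) {
    peaks <- rtracklayer::import(config$peaksBed, format = "bed")
    summary$h3k9me2 <- list(
      occupancy = occupancyFraction(peaks, genome))
    if (!is.null(ltr)) {
      ov <- elementOverlap(ltr, peaks)
      ct <- buildContingency(ltr, peaks, genome)
      fish <- fisherExactTest(ct)
      out$fisher <- fish
      summary$h3k9me2$ltr_overlap <- ov
      summary$h3k9me2$fisher <- list(
        n11 = ct$n11, n12 = ct$n12, n21 = ct$n21, n22 = ct$n22,
        odds_ratio = fish$odds_ratio, p_greater = fish$p_greater,
        p_two_sided = fish$p_two_sided)
    }
  }
  if (!is.null(config$srnaReads)) {
    lens <- readLengths(config$srnaReads)
    prof <- sizeProfile(lens, config$srnaRange[1], config$srnaRange[2])
    out$srna <- prof
    summary$srna <- list(
      total_in_range = prof$total_in_range,
      total_seen = prof$total_seen,
      fraction = stats::setNames(as.list(prof$profile$fraction),
                                 prof$profile$length))
  }
  out$summary <- summary
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) data.table::fwrite(
      df, file.path(outDir, f), sep = "\t")
    w(global, "global_levels.tsv")
    w(winMeth, "window_levels.tsv")
    w(subctx, "subcontext_levels.tsv")
    w(dyads, "dyad_levels.tsv")
    w(meta, "metaplot.tsv")
    w(gbm, "gene_enrichment.tsv")
    if (!is.null(out$ltrCalls)) w(out$ltrCalls, "ltr_enrichment.tsv")
    if (!is.null(out$srna)) w(out$srna$profile, "srna_profile.tsv")
    sj <- summary
    sj$config <- NULL
    jsonlite::write_json(sj, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(out)
}
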