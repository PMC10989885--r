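#' Collect per-feature methylation counts
#'
#' Aggregates a Methylome over the counted positions of each feature: coding
#' exonic positions for genes, the full first-to-last-bp span for
#' transposons. Both counting bases are collected: read counts (mc_sum /
#' cov_sum over covered sites) and site counts (methylated sites / total
#' sites with coverage >= \code{minCovSite}; requires prior
#' \code{\link{callSites}} for the methylated column).
#'
#' @param meth a \code{\link{Methylome}}
#' @param regionsByFeature named \code{GRangesList} (or list of
#'   \code{GRanges}): the counted positions of each feature
#' @param minCovSite minimum coverage for a site to enter the site-count
#'   basis (default 3)
#' @return \code{data.frame}: feature_id x context with mc_sum, cov_sum,
#'   n_sites, n_methylated (NA when sites were never called)
#' @export
collectFeatureCounts <- function(meth, regionsByFeature, minCovSite = 3L) {
  gr <- methSites(meth)
  m <- S4Vectors::mcols(gr)
  keep <- m$context %in% c("CG", "CHG", "CHH") & m$cov >= 1L
  gr <- gr[keep]; m <- m[keep, , drop = FALSE]
  hasCalls <- "methylated" %in% colnames(m)
  ids <- names(regionsByFeature)
  if (is.null(ids)) stop("regionsByFeature must be named by feature id")
  flat <- unlist(GenomicRanges::GRangesList(lapply(regionsByFeature, function(g)
    GenomicRanges::reduce(g, ignore.strand = TRUE))), use.names = FALSE)
  fid <- rep(ids, vapply(regionsByFeature, function(g)
    length(GenomicRanges::reduce(g, ignore.strand = TRUE)), integer(1)))
  suppressWarnings(hits <- GenomicRanges::findOverlaps(
    gr, flat, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  dt <- data.table::data.table(
    feature_id = fid[S4Vectors::subjectHits(hits)],
    context = m$context[qi],
    mc = as.numeric(m$mc[qi]), cov = as.numeric(m$cov[qi]),
    deep = m$cov[qi] >= minCovSite,
    meth = if (hasCalls) m$methylated[qi] & m$cov[qi] >= minCovSite else NA)
  ## feature ranges are reduced per feature, so a site hits each feature once
  agg <- dt[, list(mc_sum = sum(mc), cov_sum = sum(cov),
                   n_sites = sum(deep),
                   n_methylated = if (hasCalls) sum(meth, na.rm = TRUE) else
                     NA_integer_),
            by = c("feature_id", "context")]
  grid <- data.table::CJ(feature_id = ids, context = c("CG", "CHG", "CHH"))
  out <- as.data.frame(agg[grid, on = c("feature_id", "context")])
  zero <- is.na(out$mc_sum)
  out$mc_sum[zero] <- 0; out$cov_sum[zero] <- 0; out$n_sites[zero] <- 0L
  if (hasCalls) out$n_methylated[zero] <- 0L
  out[order(match(out$feature_id, ids), out$context), , drop = FALSE]
}

#' Background methylation rates across all counted feature positions
#'
#' The probability of success for the per-feature binomial test: per
#' context, the weighted methylation level pooled over all counted positions
#' of all features (reads basis), or the pooled fraction of methylated sites
#' (sites basis).
#'
#' @param counts output of \code{\link{collectFeatureCounts}}
#' @param basis "reads" or "sites"
#' @return named numeric vector p0 per context
#' @export
backgroundRates <- function(counts, basis = c("reads", "sites")) {
  basis <- match.arg(basis)
  sp <- split(counts, counts$context)
  vapply(sp, function(d) {
    if (basis == "reads") {
      if (sum(d$cov_sum) > 0) sum(d$mc_sum) / sum(d$cov_sum) else NA_real_
    } else {
      if (sum(d$n_sites) > 0) sum(d$n_methylated) / sum(d$n_sites) else
        NA_real_
    }
  }, numeric(1))
}

#' One-sided binomial enrichment p-value
#'
#' Upper-tail binomial probability P(X >= successes | trials, p0), the
#' per-feature enrichment test against the background rate.
#'
#' @param successes,trials nonnegative integers (vectorized)
#' @param p0 background probability of success
#' @return p-values
#' @export
binomialEnrichment <- function(successes, trials, p0) {
  if (any(successes > trials)) stop("successes must not exceed trials")
  if (any(successes < 0) || any(trials < 0)) stop("counts must be >= 0")
  if (length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1) {
    stop("p0 must be a single probability in [0,1]")
  }
  if (p0 == 0) return(ifelse(successes > 0, 0, 1))
  if (p0 == 1) return(rep(1, length(successes)))
  stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' @param p p-values in [0,1]
#' @return step-up adjusted q-values (\code{stats::p.adjust}, method "BH")
#' @export
bhCorrect <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Methylation class from per-context enrichment flags
#'
#' gbM (gene-body methylation) requires CG enrichment without CHG or CHH
#' enrichment; any CHG or CHH enrichment is "CHG/CHH-enriched"; no
#' enrichment is "unmethylated". Features whose flags are all NA (never
#' tested) are "insufficient-data".
#'
#' @param cg,chg,chh logical enrichment flags (q < alpha), NA when untested
#' @return character vector of classes
#' @export
classifyFeature <- function(cg, chg, chh) {
  n <- max(length(cg), length(chg), length(chh))
  cg <- rep_len(cg, n); chg <- rep_len(chg, n); chh <- rep_len(chh, n)
  out <- rep("unmethylated", n)
  out[is.na(cg) & is.na(chg) & is.na(chh)] <- "insufficient-data"
  cgT <- !is.na(cg) & cg; chgT <- !is.na(chg) & chg; chhT <- !is.na(chh) & chh
  out[chgT | chhT] <- "CHG/CHH-enriched"
  out[cgT & !chgT & !chhT] <- "gbM"
  out
}

#' Per-feature methylation-enrichment calls and gbM classification
#'
#' The full per-feature pipeline: collect counts over each feature's counted
#' positions, derive per-context background rates from the pooled counts,
#' apply the one-sided binomial enrichment test per feature and context,
#' correct with Benjamini-Hochberg FDR within each context over all tested
#' features, flag enrichment at q < alpha, and classify (gbM /
#' CHG/CHH-enriched / unmethylated / insufficient-data).
#'
#' @inheritParams collectFeatureCounts
#' @param basis counting basis: "reads" (methylated reads vs total reads)
#'   or "sites" (methylated sites vs total sites; requires
#'   \code{\link{callSites}} first)
#' @param alpha FDR threshold (default 0.05)
#' @return \code{data.frame}: one row per feature with successes/trials,
#'   p/q/enriched per context, and \code{class}
#' @export
callFeatureEnrichment <- function(meth, regionsByFeature,
                                  basis = c("reads", "sites"),
                                  alpha = 0.05, minCovSite = 3L) {
  basis <- match.arg(basis)
  counts <- collectFeatureCounts(meth, regionsByFeature, minCovSite)
  if (basis == "sites" && all(is.na(counts$n_methylated))) {
    stop("sites basis requires callSites() before feature enrichment")
  }
  p0 <- backgroundRates(counts, basis)
  ids <- unique(counts$feature_id)
  out <- data.frame(feature_id = ids, basis = basis,
                    stringsAsFactors = FALSE)
  for (ctx in c("CG", "CHG", "CHH")) {
    d <- counts[counts$context == ctx, , drop = FALSE]
    d <- d[match(ids, d$feature_id), , drop = FALSE]
    if (basis == "reads") {
      succ <- d$mc_sum; tri <- d$cov_sum
    } else {
      succ <- d$n_methylated; tri <- d$n_sites
    }
    p <- rep(NA_real_, length(ids))
    testable <- tri >= 1 & !is.na(p0[ctx])
    if (any(testable)) {
      p[testable] <- binomialEnrichment(succ[testable], tri[testable],
                                        p0[ctx])
    }
    q <- rep(NA_real_, length(ids))
    q[testable] <- bhCorrect(p[testable])
    out[[paste0("successes_", ctx)]] <- succ
    out[[paste0("trials_", ctx)]] <- tri
    out[[paste0("p_", ctx)]] <- p
    out[[paste0("q_", ctx)]] <- q
    out[[paste0("enriched_", ctx)]] <- ifelse(is.na(q), NA, q < alpha)
  }
  out$class <- classifyFeature(out$enriched_CG, out$enriched_CHG,
                               out$enriched_CHH)
  attr(out, "background") <- p0
  out
}

#' Fraction of enriched features, rounded as printed
#'
#' @param nEnriched,nTotal counts, 0 <= nEnriched <= nTotal, nTotal > 0
#' @param decimals digits to keep (half-away-from-zero rounding)
#' @return rounded fraction
#' @export
enrichedFraction <- function(nEnriched, nTotal, decimals = 3L) {
  if (any(nTotal <= 0)) stop("nTotal must be positive")
  if (any(nEnriched < 0 | nEnriched > nTotal)) {
    stop("need 0 <= nEnriched <= nTotal")
  }
  x <- nEnriched / nTotal
  sign(x) * floor(abs(x) * 10^decimals + 0.5) / 10^decimals
}

#' Cross-genotype overlap of gbM gene sets
#'
#' Counts ortholog pairs whose members are gbM in both genotypes. The
#' ortholog map is an externally produced one-to-one pairing of feature ids.
#'
#' @param gbmA,gbmB character vectors of gbM feature ids in each genotype
#' @param orthologMap \code{data.frame} with columns \code{id_a},
#'   \code{id_b}
#' @return list: \code{overlap} (pairs gbM in both), \code{jaccard}
#'   (overlap / pairs gbM in either), \code{unmappedA}, \code{unmappedB}
#'   (gbM ids absent from the map)
#' @export
gbmSetOverlap <- function(gbmA, gbmB, orthologMap) {
  stopifnot(all(c("id_a", "id_b") %in% colnames(orthologMap)))
  if (anyDuplicated(orthologMap$id_a) || anyDuplicated(orthologMap$id_b)) {
    stop("ortholog map must be one-to-one")
  }
  aIn <- orthologMap$id_a %in% gbmA
  bIn <- orthologMap$id_b %in% gbmB
  overlap <- sum(aIn & bIn)
  either <- sum(aIn | bIn)
  list(overlap = overlap,
       jaccard = if (either > 0) overlap / either else NA_real_,
       unmappedA = setdiff(gbmA, orthologMap$id_a),
       unmappedB = setdiff(gbmB, orthologMap$id_b))
}

#' Expression filter on FPKM
#'
#' @param fpkm nonnegative FPKM values
#' @param threshold a gene is expressed when fpkm >= threshold (default 1)
#' @return logical vector
#' @export
expressionFilter <- function(fpkm, threshold = 1) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be >= 0")
  fpkm >= threshold
}
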