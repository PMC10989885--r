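VALID_CONTEXTS <- c("CG", "CHG", "CHH", "undefined")

#' Methylome: per-cytosine methylation calls for one sample
#'
#' A \code{Methylome} holds one sample's per-cytosine methylation evidence as
#' a width-1 \code{GRanges} (one range per cytosine, at the Watson coordinate
#' of the base; minus-strand cytosines sit at the coordinate of the
#' complementary guanine, the allc convention). Metadata columns carry the
#' trinucleotide \code{subcontext} read 5'->3' on the site's own strand, the
#' derived \code{context} (CG/CHG/CHH/undefined), the methylated read count
#' \code{mc} and total read count \code{cov}. Site-calling
#' (\code{\link{callSites}}) appends \code{p}, \code{q} and
#' \code{methylated}.
#'
#' @slot sites width-1 \code{GRanges} with mcols \code{subcontext},
#'   \code{context}, \code{mc}, \code{cov}
#' @slot controlContig name of the unmethylated control contig (typically the
#'   chloroplast), or \code{NA_character_} when none is designated
#'
#' @seealso \code{\link{readAllc}}, \code{\link{weightedMethylation}},
#'   \code{\link{callSites}}
#' @export
setClass("Methylome",
  representation(sites = "GRanges", controlContig = "character"),
  prototype(sites = GenomicRanges::GRanges(), controlContig = NA_character_)
)

setValidity("Methylome", function(object) {
  msg <- character()
  gr <- object@sites
  m <- S4Vectors::mcols(gr)
  need <- c("subcontext", "context", "mc", "cov")
  if (!all(need %in% colnames(m))) {
    return(paste("sites must carry mcols:", paste(need, collapse = ", ")))
  }
  if (length(gr)) {
    if (any(GenomicRanges::width(gr) != 1L)) {
      msg <- c(msg, "all sites must have width 1")
    }
    if (!all(m$context %in% VALID_CONTEXTS)) {
      msg <- c(msg, "context must be CG, CHG, CHH or undefined")
    }
    if (any(m$cov < 0L) || any(m$mc < 0L) || any(m$mc > m$cov)) {
      msg <- c(msg, "counts must satisfy 0 <= mc <= cov")
    }
    if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-"))) {
      msg <- c(msg, "every site must be stranded (+/-)")
    }
  }
  if (length(object@controlContig) != 1L) {
    msg <- c(msg, "controlContig must be a single string (or NA)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Methylome
#'
#' @param sites width-1 stranded \code{GRanges} with mcols \code{subcontext},
#'   \code{context}, \code{mc}, \code{cov}
#' @param controlContig optional name of the unmethylated control contig
#' @return a \code{Methylome}
#' @export
Methylome <- function(sites, controlContig = NA_character_) {
  new("Methylome", sites = sites, controlContig = as.character(controlContig))
}

#' @describeIn Methylome the underlying per-site \code{GRanges}
#' @param x,object a \code{Methylome}
#' @export
methSites <- function(x) x@sites

#' @describeIn Methylome the designated unmethylated control contig
#' @export
controlContig <- function(x) x@controlContig

#' @export
setMethod("length", "Methylome", function(x) length(x@sites))

#' @export
setMethod("show", "Methylome", function(object) {
  gr <- object@sites
  ctx <- table(factor(S4Vectors::mcols(gr)$context, levels = VALID_CONTEXTS))
  cat("Methylome with", length(gr), "cytosine sites on",
      length(GenomeInfoDb::seqlevels(gr)), "contig(s)\n")
  cat("  contexts:", paste(sprintf("%s=%d", names(ctx), as.integer(ctx)),
                           collapse = " "), "\n")
  if (!is.na(object@controlContig)) {
    cat("  control contig:", object@controlContig, "\n")
  }
  if ("methylated" %in% colnames(S4Vectors::mcols(gr))) {
    cat("  site calls present (", sum(S4Vectors::mcols(gr)$methylated,
                                      na.rm = TRUE),
        " methylated)\n", sep = "")
  }
})
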