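## Shared fixtures and independent oracles. The oracles deliberately use
## different code paths (regex scans, explicit summations, plain choose())
## than the package implementation they check.

makeGenome <- function(..., control = NA_character_) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    organelle = names(g) %in% control)
  S4Vectors::metadata(g) <- list(controlContig = control)
  g
}

## Build a Methylome directly from site vectors
makeMeth <- function(chrom, pos, strand, subcontext, mc, cov,
                     control = NA_character_) {
  ctx <- duckmeth:::.classifyTriplet(subcontext)$context
  ctx[nchar(subcontext) < 3] <- "undefined"
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = 1L), strand,
    subcontext = subcontext, context = ctx,
    mc = as.integer(mc), cov = as.integer(cov))
  Methylome(gr, control)
}

## Independent context oracle: regex scan of the sequence and its reverse
## complement, mapping crick coordinates back by L + 1 - j.
oracleSites <- function(seq) {
  scan1 <- function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- nchar(s)
    idx <- which(chars == "C")
    out <- data.frame(pos = idx, context = "undefined",
                      stringsAsFactors = FALSE)
    full <- idx[idx <= L - 2]
    tri <- substring(s, full, full + 2)
    cls <- ifelse(grepl("^CG", tri), "CG",
           ifelse(grepl("^C[ACT]G$", tri), "CHG",
           ifelse(grepl("^C[ACT][ACT]$", tri), "CHH", "undefined")))
    out$context[match(full, out$pos)] <- cls
    out
  }
  L <- nchar(seq)
  w <- scan1(seq)
  w$strand <- "+"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  cr <- scan1(rc)
  cr$pos <- L + 1 - cr$pos
  cr$strand <- "-"
  out <- rbind(w, cr)
  out <- out[order(out$pos, out$strand), c("pos", "strand", "context")]
  rownames(out) <- NULL
  out
}

## Direct-summation binomial upper tail: P(X >= k | n, p)
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

## Exhaustive hypergeometric enumeration via plain choose()
oracleFisher <- function(n11, n12, n21, n22) {
  m1 <- n11 + n12; m2 <- n21 + n22; K <- n11 + n21; N <- m1 + m2
  support <- max(0, K - m2):min(m1, K)
  pmf <- choose(m1, support) * choose(m2, K - support) / choose(N, K)
  obs <- pmf[support == n11]
  list(p_greater = sum(pmf[support >= n11]),
       p_two_sided = sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

randomSeqStr <- function(len, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Small, fast generator configuration for unit tests
smallConfig <- function(seed = 11L, ...) {
  args <- list(seed = seed, nChroms = 2L, chromLenBp = 20000L,
               nGenes = 16L, nLtr = 10L, nSrna = 2000L,
               chloroplastLenBp = 4000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthConfig, args)
}
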