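test_that("trinucleotide classification follows the context definitions", {
  res <- classifyContext(c("CGA", "CGG", "CAG", "CTG", "CCG",
                           "CTA", "CAA", "CCC", "CGN"))
  expect_equal(res$context,
               c("CG", "CG", "CHG", "CHG", "CHG",
                 "CHH", "CHH", "CHH", "CG"))
  expect_equal(res$symmetry,
               c("CG-dyad", "CG-dyad", "CWG-dyad", "CWG-dyad", "CCG",
                 "CHH", "CHH", "CHH", "CG-dyad"))
  ## CWA: second base A/T, third base A
  expect_equal(classifyContext(c("CTA", "CAA", "CAT", "CCA"))$cwa,
               c(TRUE, TRUE, FALSE, FALSE))
  ## N makes the call undefined unless CG is already decided by base 2
  expect_equal(classifyContext(c("CNG", "CAN"))$context,
               c("undefined", "undefined"))
  expect_error(classifyContext("AGG"), "first base")
  expect_error(classifyContext("CG"), "3 bases")
})

test_that("cytosine enumeration matches a hand scan of CCGG", {
  g <- makeGenome(chr1 = "CCGG")
  s <- cytosineSites(g)
  df <- data.frame(pos = GenomicRanges::start(s),
                   strand = as.character(GenomicRanges::strand(s)),
                   sub = s$subcontext, ctx = s$context)
  expect_equal(df$pos, 1:4)
  expect_equal(df$strand, c("+", "+", "-", "-"))
  expect_equal(df$sub, c("CCG", "CGG", "CGG", "CCG"))
  expect_equal(df$ctx, c("CHG", "CG", "CG", "CHG"))
  expect_length(cytosineSites(makeGenome(chr1 = "AAAA")), 0)
})

test_that("enumeration agrees with the regex oracle on random sequences", {
  set.seed(42)
  for (i in 1:25) {
    seq <- randomSeqStr(500)
    g <- makeGenome(chr1 = seq)
    s <- cytosineSites(g)
    got <- data.frame(pos = GenomicRanges::start(s),
                      strand = as.character(GenomicRanges::strand(s)),
                      context = s$context, stringsAsFactors = FALSE)
    got <- got[order(got$pos, got$strand), ]
    rownames(got) <- NULL
    want <- oracleSites(seq)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("site sets are mirror-identical under reverse complement", {
  set.seed(7)
  for (i in 1:10) {
    seq <- randomSeqStr(400)
    L <- nchar(seq)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    a <- cytosineSites(makeGenome(chr1 = seq))
    b <- cytosineSites(makeGenome(chr1 = rc))
    ## map b back onto a's coordinates with strands swapped
    bmap <- data.frame(
      pos = L + 1 - GenomicRanges::start(b),
      strand = ifelse(as.character(GenomicRanges::strand(b)) == "+",
                      "-", "+"),
      sub = b$subcontext, ctx = b$context)
    bmap <- bmap[order(bmap$pos, bmap$strand), ]
    amap <- data.frame(pos = GenomicRanges::start(a),
                       strand = as.character(GenomicRanges::strand(a)),
                       sub = a$subcontext, ctx = a$context)
    amap <- amap[order(amap$pos, amap$strand), ]
    expect_equal(amap$pos, bmap$pos)
    expect_equal(amap$strand, bmap$strand)
    expect_equal(amap$ctx, bmap$ctx)
    expect_equal(amap$sub, bmap$sub)
  }
})

test_that("context counts conserve the total C+G base count", {
  set.seed(3)
  seq <- randomSeqStr(2000)
  g <- makeGenome(chr1 = seq)
  s <- cytosineSites(g)
  nCG <- sum(strsplit(seq, "")[[1]] %in% c("C", "G"))
  expect_equal(length(s), nCG)
  expect_equal(sum(table(s$context)), nCG)
})

test_that("dyad pairing follows the CG/CWG rules and excludes CCG", {
  ## ACGT: one CG dyad at (2,3)
  s <- cytosineSites(makeGenome(chr1 = "ACGT"))
  d <- pairDyads(s)
  expect_equal(nrow(d), 1L)
  expect_equal(GenomicRanges::start(s)[d$watson], 2L)
  expect_equal(GenomicRanges::start(s)[d$crick], 3L)
  expect_equal(d$kind, "CG")
  ## CAGCTG: two CWG dyads, offsets of 2
  s2 <- cytosineSites(makeGenome(chr1 = "CAGCTG"))
  d2 <- pairDyads(s2)
  expect_equal(d2$kind, c("CWG", "CWG"))
  expect_equal(GenomicRanges::start(s2)[d2$watson], c(1L, 4L))
  expect_equal(GenomicRanges::start(s2)[d2$crick], c(3L, 6L))
  ## CCGG: only the central CG dyad; CCG sites stay unpaired
  s3 <- cytosineSites(makeGenome(chr1 = "CCGG"))
  d3 <- pairDyads(s3)
  expect_equal(d3$kind, "CG")
  expect_equal(GenomicRanges::start(s3)[d3$watson], 2L)
  ## with includeCCG, CCG pairs with the opposite-strand cytosine
  d3c <- pairDyads(s3, includeCCG = TRUE)
  expect_true("CCG" %in% d3c$kind)
})

test_that("dyad pairing is an involution: each site in at most one dyad", {
  set.seed(12)
  for (i in 1:5) {
    s <- cytosineSites(makeGenome(chr1 = randomSeqStr(800)))
    d <- pairDyads(s)
    expect_false(any(duplicated(c(d$watson, d$crick))))
    ## CWG partners are mutual reverse complements (palindromic span)
    cwg <- d$kind == "CWG"
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s$subcontext[d$crick][cwg])))
    expect_equal(s$subcontext[d$watson][cwg], rc)
    ## CG partners share the palindromic dinucleotide at offset 1
    cg <- d$kind == "CG"
    expect_true(all(GenomicRanges::start(s)[d$crick][cg] -
                      GenomicRanges::start(s)[d$watson][cg] == 1L))
    expect_true(all(s$context[d$watson][cg] == "CG" &
                      s$context[d$crick][cg] == "CG"))
  }
})

test_that("genome tiling produces half-open consecutive windows", {
  w <- tileWindows(c(chr1 = 120000), 50000)
  expect_equal(GenomicRanges::start(w), c(1, 50001, 100001))
  expect_equal(GenomicRanges::end(w), c(50000, 100000, 120000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  w2 <- tileWindows(c(chr1 = 50000), 50000)
  expect_length(w2, 1)
  expect_false(w2$partial)
  expect_error(tileWindows(c(chr1 = 100), 0), "width")
})

test_that("interval helpers use half-open overlap semantics", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_true(intervalsOverlap(
    a, GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160))))
  ## adjacent intervals do not overlap
  expect_false(intervalsOverlap(
    a, GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 210))))
  m <- mergeIntervals(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 6), c(10, 20))))
  expect_length(m, 1)
  expect_equal(coveredBp(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 6), c(10, 20)))), 20)
  expect_error(
    coveredBp(GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 5)),
              genome = c(chr1 = 100)),
    "unknown chromosome")
})

test_that("FASTA reading folds case, validates names and alphabet", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt"), fa)
  g <- readGenome(fa)
  expect_equal(names(g), "chr1")
  expect_equal(as.character(g[[1]]), "ACGT")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa)
  expect_error(readGenome(fa), "duplicate")
  writeLines(c(">chr1", "ACGX"), fa)
  expect_error(readGenome(fa), "non-IUPAC")
})
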