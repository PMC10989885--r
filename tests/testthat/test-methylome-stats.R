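test_that("allc round-trip preserves records and validates counts", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">Chr01", paste(rep("ACGT", 50), collapse = "")), fa)
  g <- readGenome(fa)
  allc <- tempfile(fileext = ".tsv")
  writeLines(c("Chr01\t2\t+\tCGT\t3\t10\t1",
               "Chr01\t3\t-\tCGT\t0\t5\t1"), allc)
  meth <- readAllc(allc, g)
  expect_s4_class(meth, "Methylome")
  expect_equal(length(meth), 2L)
  s <- methSites(meth)
  expect_equal(GenomicRanges::start(s), c(2L, 3L))
  expect_equal(s$context, c("CG", "CG"))
  expect_equal(s$mc, c(3L, 0L))
  ## write and re-read
  out <- tempfile(fileext = ".tsv")
  writeAllc(meth, out)
  again <- readAllc(out, g)
  expect_equal(as.data.frame(methSites(again)), as.data.frame(s))
  ## mc > cov is a row error with line number
  writeLines("Chr01\t2\t+\tCGT\t11\t10\t1", allc)
  expect_error(readAllc(allc), "line")
  ## wrong reference base
  writeLines("Chr01\t1\t+\tCGT\t1\t10\t1", allc)
  expect_error(readAllc(allc, g), "cytosine")
  ## unknown chromosome
  writeLines("Chr99\t2\t+\tCGT\t1\t10\t1", allc)
  expect_error(readAllc(allc, g), "absent")
  ## empty file warns and yields an empty Methylome
  file.create(allc)
  expect_warning(m0 <- readAllc(allc), "empty")
  expect_equal(length(m0), 0L)
})

test_that("nonconversion is the pooled level of the control contig", {
  meth <- makeMeth(c("chrC", "chrC", "chr1"), c(10, 20, 5),
                   c("+", "+", "+"), c("CGA", "CTA", "CGA"),
                   mc = c(3, 2, 50), cov = c(500, 500, 100),
                   control = "chrC")
  nc <- estimateNonconversion(meth)
  expect_equal(nc$epsilon, 5 / 1000)
  expect_equal(nc$covSum, 1000)
  ## zero methylated reads -> epsilon 0
  m0 <- makeMeth("chrC", 10, "+", "CGA", 0, 100, control = "chrC")
  expect_equal(estimateNonconversion(m0)$epsilon, 0)
  ## no control records -> error
  m1 <- makeMeth("chr1", 10, "+", "CGA", 1, 10, control = "chrC")
  expect_error(estimateNonconversion(m1), "control contig")
})

test_that("site calls match the binomial tail and respect BH within context", {
  ## p for fully methylated 3x site collapses to epsilon^3
  meth <- makeMeth("chr1", c(2, 10, 20), rep("+", 3),
                   c("CGA", "CGA", "CGA"),
                   mc = c(3, 0, 2), cov = c(3, 10, 10))
  called <- callSites(meth, epsilon = 0.005)
  p <- methSites(called)$p
  expect_equal(p[1], 0.005^3, tolerance = 1e-12)
  expect_equal(p[2], 1.0)
  called2 <- callSites(makeMeth("chr1", 2, "+", "CGA", 2, 10),
                       epsilon = 0.05)
  expect_equal(methSites(called2)$p, oracleBinomTail(2, 10, 0.05),
               tolerance = 1e-12)
  expect_error(callSites(meth, epsilon = 1.5), "epsilon")
  ## q >= p and q monotone in sorted p order, per context batch
  set.seed(5)
  n <- 300
  mm <- makeMeth("chr1", seq_len(n) * 5, rep("+", n),
                 sample(c("CGA", "CAG", "CAA"), n, TRUE),
                 mc = rbinom(n, 10, 0.05), cov = rep(10, n))
  cc <- callSites(mm, epsilon = 0.01)
  s <- methSites(cc)
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- s$context == ctx
    expect_true(all(s$q[sel] >= s$p[sel] - 1e-12))
    o <- order(s$p[sel])
    expect_true(all(diff(s$q[sel][o]) >= -1e-12))
    expect_equal(s$q[sel], p.adjust(s$p[sel], "BH"))
  }
})

test_that("weighted methylation applies the coverage floor per site", {
  meth <- makeMeth("chr1", c(2, 10), c("+", "+"), c("CGA", "CGA"),
                   mc = c(2, 0), cov = c(4, 6))
  expect_equal(weightedMethylation(meth, minCov = 1)$level[1], 0.2)
  expect_equal(weightedMethylation(meth, minCov = 5)$level[1], 0.0)
  ## no qualifying site -> NA
  expect_true(is.na(weightedMethylation(meth, minCov = 7)$level[1]))
  ## invariant to record order and partition merging
  set.seed(8)
  n <- 200
  mm <- makeMeth("chr1", sample(10000, n), rep("+", n), rep("CGA", n),
                 mc = rbinom(n, 10, 0.3), cov = rep(10, n))
  w1 <- weightedMethylation(mm, minCov = 5)
  perm <- makeMeth("chr1", rev(GenomicRanges::start(methSites(mm))),
                   rep("+", n), rep("CGA", n),
                   mc = rev(methSites(mm)$mc),
                   cov = rev(methSites(mm)$cov))
  expect_equal(weightedMethylation(perm, minCov = 5), w1)
})

test_that("window levels partition the genome-wide totals", {
  set.seed(9)
  n <- 400
  meth <- makeMeth("chr1", sample(99000, n), rep("+", n), rep("CGA", n),
                   mc = rbinom(n, 12, 0.2), cov = rep(12, n))
  win <- tileWindows(c(chr1 = 100000), 20000)
  wm <- windowedMethylation(meth, win, contexts = "CG", minCov = 5)
  gl <- weightedMethylation(meth, contexts = "CG", minCov = 5)
  expect_equal(sum(wm$mc_sum), gl$mc_sum)
  expect_equal(sum(wm$cov_sum), gl$cov_sum)
  ## a window with no sites reports NA
  empty <- makeMeth("chr1", 5, "+", "CGA", 1, 10)
  wm2 <- windowedMethylation(empty, win, contexts = "CG", minCov = 5)
  expect_true(all(is.na(wm2$level[2:5])))
})

test_that("subcontext rollups follow the CWA and CWG definitions", {
  meth <- makeMeth("chr1", c(5, 10, 15, 20, 25), rep("+", 5),
                   c("CAA", "CAT", "CAG", "CTG", "CCG"),
                   mc = c(1, 2, 1, 1, 2), cov = c(10, 10, 10, 10, 10))
  sc <- subcontextSummary(meth, minCov = 1)
  roll <- function(lbl) sc$level[sc$label == lbl & sc$kind == "rollup"]
  expect_equal(roll("CWA"), 0.1)          # CAA only (third base A)
  expect_equal(roll("CHH-nonCWA"), 0.2)   # CAT
  expect_equal(roll("CWG"), 2 / 20)       # CAG + CTG
  expect_equal(roll("CCG"), 0.2)
  ## empty methylome: all levels NA
  e <- makeMeth(character(), integer(), character(), character(),
                integer(), integer())
  expect_equal(nrow(subcontextSummary(e)), 7)  # rollups only, all NA
})

test_that("dyad levels report per-strand levels above the coverage floor", {
  ## ACGT with watson 4/4 and crick 0/4
  meth <- makeMeth("chr1", c(2, 3), c("+", "-"), c("CGT", "CGT"),
                   mc = c(4, 0), cov = c(4, 4))
  d <- dyadLevels(meth, minCov = 3)
  expect_equal(nrow(d), 1L)
  expect_equal(d$watson_level, 1.0)
  expect_equal(d$crick_level, 0.0)
  expect_equal(d$delta, 1.0)
  ## a strand below the floor drops the dyad
  meth2 <- makeMeth("chr1", c(2, 3), c("+", "-"), c("CGT", "CGT"),
                    mc = c(2, 0), cov = c(2, 4))
  expect_equal(nrow(dyadLevels(meth2, minCov = 3)), 0L)
  expect_equal(nrow(dyadLevels(meth2, minCov = 2)), 1L)
})

test_that("independent strands decorrelate dyad levels", {
  set.seed(21)
  cfg <- smallConfig(seed = 21, symmetricMaintenance = FALSE,
                     coverageMean = 30)
  gen <- generateGenome(cfg)
  sim <- generateMethylome(gen, cfg)
  d <- dyadLevels(sim$meth, minCov = 3, kinds = "CG")
  expect_gt(nrow(d), 1000)
  expect_lt(abs(cor(d$watson_level, d$crick_level)), 0.1)
})

test_that("metaplot windows map positions in 5'->3' locus order", {
  ## gene of length 200 on +: body windows exactly 10 bp; put one site in
  ## each body window with level = window index / 20
  pos <- 1001 + (0:19) * 10   # first bp of each body window
  meth <- makeMeth("chr1", pos, rep("+", 20), rep("CGA", 20),
                   mc = 0:19, cov = rep(19, 20))
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200), "+")
  mp <- metaplotProfile(meth, gene, flankBp = 1000, nWindows = 20,
                        contexts = "CG", minCov = 1)
  body <- mp[mp$segment == "body", ]
  expect_equal(body$level, (0:19) / 19)
  ## the same locus on minus strand reverses the body profile
  geneM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200), "-")
  mpM <- metaplotProfile(meth, geneM, flankBp = 1000, nWindows = 20,
                         contexts = "CG", minCov = 1)
  expect_equal(mpM[mpM$segment == "body", "level"], (19:0) / 19)
  ## flank windows are fixed flankBp/nWindows = 50 bp: a site 1 bp
  ## upstream falls in upstream window 20; 1 bp downstream in window 41
  methF <- makeMeth("chr1", c(1000, 1201), c("+", "+"), c("CGA", "CGA"),
                    mc = c(5, 7), cov = c(10, 10))
  mpF <- metaplotProfile(methF, gene, flankBp = 1000, nWindows = 20,
                         contexts = "CG", minCov = 1)
  expect_equal(mpF$level[mpF$window == 20], 0.5)
  expect_equal(mpF$level[mpF$window == 41], 0.7)
  ## exonic mask restricts body windows only
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
  mpE <- metaplotProfile(meth, gene, flankBp = 1000, nWindows = 20,
                         exonic = mask, contexts = "CG", minCov = 1)
  bodyE <- mpE[mpE$segment == "body", ]
  expect_equal(bodyE$n_sites, rep(c(1L, 0L), each = 10))
  ## loci shorter than nWindows are skipped with a warning
  tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  expect_warning(
    metaplotProfile(meth, c(gene, tiny), flankBp = 1000, nWindows = 20,
                    contexts = "CG", minCov = 1),
    "skipped")
})
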