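test_that("feature counts respect the coding-exonic restriction", {
  ## gene with two exonic CG sites (3/10) and (2/10); an intronic site must
  ## not count
  meth <- makeMeth("chr1", c(100, 300, 200), rep("+", 3),
                   rep("CGA", 3), mc = c(3, 2, 9), cov = c(10, 10, 10))
  cds <- GenomicRanges::GRangesList(
    geneA = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(90, 290), c(110, 310))))
  fc <- collectFeatureCounts(meth, cds)
  cg <- fc[fc$context == "CG", ]
  expect_equal(cg$mc_sum, 5)
  expect_equal(cg$cov_sum, 20)
  expect_equal(cg$n_sites, 2L)
  ## sites basis after calling: both sites methylated -> (2, 2)
  called <- callSites(meth, epsilon = 0.005)
  fc2 <- collectFeatureCounts(called, cds)
  cg2 <- fc2[fc2$context == "CG", ]
  expect_equal(cg2$n_methylated, 2L)
  ## a feature with no counted positions is classified insufficient-data
  cds2 <- c(cds, GenomicRanges::GRangesList(
    geneB = GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))))
  calls <- callFeatureEnrichment(called, cds2, basis = "reads")
  expect_equal(calls$class[calls$feature_id == "geneB"],
               "insufficient-data")
})

test_that("binomial enrichment matches the direct-summation oracle", {
  expect_equal(binomialEnrichment(30, 100, 0.10),
               oracleBinomTail(30, 100, 0.10), tolerance = 1e-12)
  expect_equal(binomialEnrichment(0, 50, 0.3), 1.0)
  expect_equal(binomialEnrichment(10, 10, 1), 1.0)
  expect_equal(binomialEnrichment(c(0, 3), c(5, 5), 0), c(1, 0))
  expect_error(binomialEnrichment(6, 5, 0.1), "exceed")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(500, 1)
    k <- sample.int(n, 1)
    p <- runif(1, 0.01, 0.5)
    expect_equal(binomialEnrichment(k, n, p), oracleBinomTail(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("BH correction reproduces the step-up formula", {
  expect_equal(bhCorrect(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhCorrect(0.37), 0.37)
  ## independent step-up computation
  set.seed(13)
  p <- runif(40)
  m <- length(p)
  o <- order(p)
  q <- pmin(1, cummin(rev(m * p[o] / seq_len(m)))[m:1])
  expect_equal(bhCorrect(p)[o], q)
  expect_error(bhCorrect(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("classification is a pure function of the enrichment flags", {
  grid <- expand.grid(cg = c(TRUE, FALSE), chg = c(TRUE, FALSE),
                      chh = c(TRUE, FALSE))
  cls <- classifyFeature(grid$cg, grid$chg, grid$chh)
  want <- ifelse(grid$chg | grid$chh, "CHG/CHH-enriched",
                 ifelse(grid$cg, "gbM", "unmethylated"))
  expect_equal(cls, want)
  expect_equal(classifyFeature(NA, NA, NA), "insufficient-data")
  ## NA in one context with signal elsewhere still classifies
  expect_equal(classifyFeature(TRUE, NA, FALSE), "gbM")
})

test_that("enriched fractions reproduce the printed per-mille values", {
  expect_equal(enrichedFraction(3, 1114, 3), 0.003)
  expect_equal(enrichedFraction(6, 1510, 3), 0.004)
  expect_equal(enrichedFraction(0, 10, 3), 0.000)
  expect_error(enrichedFraction(1, 0), "positive")
  expect_error(enrichedFraction(5, 3), "<=")
})

test_that("gbM set overlap counts ortholog pairs gbM in both genotypes", {
  map <- data.frame(id_a = c("g1", "g2", "g3"),
                    id_b = c("h1", "h2", "h3"))
  ov <- gbmSetOverlap(c("g1", "g2"), "h1", map)
  expect_equal(ov$overlap, 1L)
  ## empty map: nothing overlaps, everything unmapped
  ov2 <- gbmSetOverlap(c("g1"), c("h1"),
                       data.frame(id_a = character(), id_b = character()))
  expect_equal(ov2$overlap, 0L)
  expect_equal(ov2$unmappedA, "g1")
  ## identity map on identical sets: full overlap, Jaccard 1
  idm <- data.frame(id_a = c("g1", "g2"), id_b = c("g1", "g2"))
  ov3 <- gbmSetOverlap(c("g1", "g2"), c("g1", "g2"), idm)
  expect_equal(ov3$overlap, 2L)
  expect_equal(ov3$jaccard, 1)
  expect_error(gbmSetOverlap("g1", "h1",
    data.frame(id_a = c("g1", "g1"), id_b = c("h1", "h2"))),
    "one-to-one")
})

test_that("expression filter uses an inclusive threshold", {
  expect_equal(expressionFilter(c(0.5, 1.0, 12.3)),
               c(FALSE, TRUE, TRUE))
  expect_error(expressionFilter(-1), ">= 0")
})

test_that("null simulations keep the realized FDR near nominal", {
  ## genes drawn at the background rate: few q < 0.05 calls expected
  set.seed(41)
  fracs <- replicate(5, {
    nGenes <- 500; nSitesPer <- 40; cov <- 20; p0true <- 0.10
    succ <- rbinom(nGenes, nSitesPer * cov, p0true)
    p0 <- sum(succ) / (nGenes * nSitesPer * cov)
    p <- binomialEnrichment(succ, rep(nSitesPer * cov, nGenes), p0)
    mean(bhCorrect(p) < 0.05)
  })
  expect_lte(mean(fracs), 0.07)
})
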