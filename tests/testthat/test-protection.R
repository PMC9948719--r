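test_that("region IPKM follows its closed form", {
  g <- toyGenome(2000000)
  # exactly one million unique sites, five of them in [1500000, 1500500)
  pos <- c(seq_len(999995) - 1, 1500000 + c(10, 100, 200, 300, 400))
  tis <- TisTable(g, pos)
  expect_equal(totalUnique(tis), 1e6)
  rs <- bindingRegionSet("toy", 1500000, 1500500)
  ri <- regionIpkm(rs, tis)
  expect_equal(ipkmValues(ri), 10.0)   # 5 * 1e9 / (500 * 1e6)
  # zero sites -> 0
  expect_equal(ipkmValues(regionIpkm(bindingRegionSet("z", 1800000, 1800500),
                                     tis)), 0)
  # mean over two disjoint equal-length regions is the average
  two <- regionIpkm(bindingRegionSet("t", c(1500000, 1800000),
                                     c(1500500, 1800500)), tis)
  expect_equal(two@mean, mean(c(10, 0)))
  expect_error(regionIpkm(bindingRegionSet("e", numeric(0), numeric(0)),
                          tis), "empty")
})

test_that("random region sampling is reproducible and size-faithful", {
  g <- toyGenome(10000)
  sets1 <- sampleRandomRegions(rep(100, 3), g, nSets = 2, seed = 5)
  sets2 <- sampleRandomRegions(rep(100, 3), g, nSets = 2, seed = 5)
  expect_identical(sets1, sets2)
  expect_length(sets1, 2)
  for (s in sets1) {
    expect_equal(nrow(s), 3)
    expect_equal(s$end - s$start, rep(100, 3))
    expect_true(all(s$start >= 0 & s$start < 10000))
  }
  expect_false(identical(sets1,
                         sampleRandomRegions(rep(100, 3), g, 2, seed = 6)))
  expect_error(sampleRandomRegions(20000, g, 1, 1), "exceeds")
})

test_that("null means are unbiased for the genome-wide density", {
  tis <- makeUniformTis(L = 200000, n = 20000, seed = 3)
  rs <- bindingRegionSet("u", seq(0, 49000, by = 1000),
                         seq(0, 49000, by = 1000) + 500)
  res <- bootstrapProtectionTest(rs, tis, nSets = 10000, seed = 9)
  expect_equal(mean(nullMeans(res)), genomeMeanIpkm(tis), tolerance = 0.02)
})

test_that("maximal depletion attains the minimal empirical p", {
  # dense uniform background that leaves two windows completely empty
  L <- 100000
  pos <- setdiff(seq(0, L - 1, by = 2), c(seq(20000, 20499), seq(60000, 60499)))
  tis <- TisTable(toyGenome(L), pos)
  rs <- bindingRegionSet("empty", c(20000, 60000), c(20500, 60500))
  res <- bootstrapProtectionTest(rs, tis, nSets = 500, seed = 2)
  expect_equal(observedIpkm(res)@mean, 0)
  expect_equal(empiricalP(res), 1 / 501)
  expect_error(bootstrapProtectionTest(
    bindingRegionSet("one", 0, 100), tis, 10, 1), "degenerate")
})

test_that("planted protection is detected by both statistics", {
  cfg <- synthConfig(genomeLength = 500000, nGenes = 0, nInsertions = 50000,
                     protectedRegionCount = 50, protectedRegionLength = 500,
                     protectionRateRatio = 0.01, seed = 13)
  g <- generateGenome(cfg)
  ann <- generateAnnotation(cfg, g)
  tis <- simulateInsertions(cfg, g, ann$truth)
  pr <- truthRegions(ann$truth)
  res <- bootstrapProtectionTest(
    bindingRegionSet("planted", pr$start, pr$end), tis,
    nSets = 1000, seed = 13)
  expect_lt(empiricalP(res), 0.05)
  expect_lt(welchP(res), 0.05)
  expect_lt(observedIpkm(res)@mean, mean(nullMeans(res)))
  # pooled Welch variant agrees on the direction
  pooled <- bootstrapProtectionTest(
    bindingRegionSet("planted", pr$start, pr$end), tis,
    nSets = 200, seed = 13, welchVariant = "pooled")
  expect_lt(welchP(pooled), 0.05)
})

test_that("empirical p is uniform when the regions are themselves random", {
  # spec'd calibration: KS uniformity over replicates at 200 null sets each
  tis <- makeUniformTis(L = 100000, n = 10000, seed = 7)
  g <- tis@genome
  ps <- vapply(1:500, function(rep) {
    obs <- sampleRandomRegions(rep(500, 10), g, nSets = 1,
                               seed = 10000 + rep)[[1]]
    empiricalP(bootstrapProtectionTest(
      bindingRegionSet("r", obs$start, obs$end), tis,
      nSets = 200, seed = 20000 + rep))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene coverage merges regions before measuring", {
  genes <- data.frame(gene_id = "g1", start = 100, end = 200)
  half <- geneRegionCoverage(genes, bindingRegionSet("p", 150, 250))
  expect_equal(half$perGene$fraction, 0.5)
  merged <- geneRegionCoverage(
    genes, bindingRegionSet("p", c(100, 140), c(160, 200)))
  expect_equal(merged$perGene$fraction, 1.0)
  none <- geneRegionCoverage(
    genes, data.frame(start = numeric(0), end = numeric(0)))
  expect_equal(none$perGene$fraction, 0)
  # pooling across proteins unions the footprints
  pooled <- geneRegionCoverage(
    genes, list(bindingRegionSet("a", 100, 160),
                bindingRegionSet("b", 140, 200)))
  expect_equal(pooled$perGene$fraction, 1.0)
  expect_equal(pooled$nAbove, 1)
})

test_that("coverage is monotone under adding regions and matches brute force", {
  set.seed(31)
  for (rep in 1:10) {
    L <- sample(5000:100000, 1)
    genes <- local({
      s <- sort(sample.int(L - 500, 15))
      data.frame(gene_id = sprintf("g%02d", 1:15), start = s,
                 end = pmin(s + sample(100:400, 15, replace = TRUE), L))
    })
    rstart <- sample.int(L - 300, 25) - 1
    rend <- rstart + sample(50:300, 25, replace = TRUE)
    fracA <- geneRegionCoverage(genes, data.frame(start = rstart[1:10],
                                                  end = rend[1:10]))
    fracB <- geneRegionCoverage(genes, data.frame(start = rstart,
                                                  end = rend))
    expect_true(all(fracB$perGene$fraction >= fracA$perGene$fraction))
    # per-base boolean-mask oracle
    mask <- logical(L)
    for (i in seq_along(rstart)) mask[(rstart[i] + 1):rend[i]] <- TRUE
    want <- vapply(seq_len(nrow(genes)), function(i)
      sum(mask[(genes$start[i] + 1):genes$end[i]]), numeric(1))
    expect_equal(fracB$perGene$covered_bp, want)
  }
})

test_that("reference overlap baseline behaves at the extremes", {
  g <- toyGenome(50000)
  tis <- makeUniformTis(L = 50000, n = 5000, seed = 1, genome = g)
  genes <- data.frame(gene_id = sprintf("r%02d", 1:20),
                      start = seq(0, 47500, by = 2500),
                      end = seq(0, 47500, by = 2500) + 800)
  none <- referenceOverlapBaseline(
    bindingRegionSet("none", numeric(0), numeric(0)), genes, g, nSets = 0)
  expect_equal(none$observed, 0)
  tiling <- referenceOverlapBaseline(
    bindingRegionSet("all", 0, 50000), genes, g, nSets = 50, seed = 2)
  expect_equal(tiling$observed, 20)
  # a random set is consistent with its own null law
  obs <- sampleRandomRegions(rep(400, 12), g, nSets = 1, seed = 77)[[1]]
  base <- referenceOverlapBaseline(
    bindingRegionSet("rand", obs$start, pmin(obs$end, 50000)),
    genes, g, nSets = 500, seed = 78)
  expect_lte(abs(base$observed - base$nullMean), 3 * base$nullSd)
})

test_that("profile correlations behave as Pearson on binned tracks", {
  g <- toyGenome(50000)
  set.seed(5)
  v <- runif(100)
  mkprof <- function(name, vals)
    binProfile(name, seq(0, 49500, by = 500), seq(500, 50000, by = 500),
               vals, g, binWidth = 500)
  p1 <- mkprof("a", v)
  expect_equal(unname(profileCorrelation(list(p1, p1))[1, 2]), 1)
  p2 <- mkprof("b", 2 * mean(v) - v)   # negation about the mean
  expect_equal(unname(profileCorrelation(list(p1, p2))[1, 2]), -1)
  # independent random profiles of 10,000 bins decorrelate
  g2 <- toyGenome(10000 * 500)
  set.seed(6)
  q1 <- binProfile("x", seq(0, 10000 * 500 - 500, by = 500),
                            seq(500, 10000 * 500, by = 500),
                            runif(10000), g2, 500)
  q2 <- binProfile("y", seq(0, 10000 * 500 - 500, by = 500),
                   seq(500, 10000 * 500, by = 500),
                   runif(10000), g2, 500)
  expect_lt(abs(profileCorrelation(list(q1, q2))[1, 2]), 0.05)
  # zero variance flagged
  flat <- binProfile("flat", 0, 50000, 1, g, 500)
  expect_warning(cm <- profileCorrelation(list(p1, flat)), "zero-variance")
  expect_true(is.na(cm[1, 2]))
  expect_equal(diag(cm), c(a = 1, flat = 1))
})

test_that("multi-set summaries carry BH-adjusted empirical p-values", {
  tis <- makeUniformTis(L = 100000, n = 10000, seed = 4)
  g <- tis@genome
  mk <- function(seed) {
    obs <- sampleRandomRegions(rep(300, 8), g, 1, seed)[[1]]
    bootstrapProtectionTest(bindingRegionSet("r", obs$start, obs$end),
                            tis, nSets = 100, seed = seed + 1)
  }
  tests <- list(a = mk(1), b = mk(2), c = mk(3))
  tab <- protectionSummaryTable(tests)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$empirical_p_bh >= tab$empirical_p))
  expect_equal(tab$empirical_p_bh,
               p.adjust(tab$empirical_p, method = "BH"))
})
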