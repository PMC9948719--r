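test_that("generated sequences honour the requested composition", {
  cfg <- synthConfig(genomeLength = 10000, gcFraction = 0, seed = 3,
                     nInsertions = 100)
  g <- generateGenome(cfg)
  freq <- Biostrings::alphabetFrequency(genomeSequence(g))
  expect_equal(sum(freq[c("G", "C")]), 0)
  expect_equal(sum(freq[c("A", "T")]), 10000)

  cfg2 <- synthConfig(genomeLength = 500000, gcFraction = 0.508, seed = 1)
  g2 <- generateGenome(cfg2)
  expect_gte(gcContent(g2), 0.498)
  expect_lte(gcContent(g2), 0.518)
})

test_that("generation is deterministic in the config seed", {
  cfg <- smallSynthConfig(seed = 11)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(genomeSequence(g1)),
                   as.character(genomeSequence(g2)))
  a1 <- generateAnnotation(cfg, g1)
  a2 <- generateAnnotation(cfg, g2)
  expect_identical(a1$genes, a2$genes)
  expect_identical(truthGenes(a1$truth), truthGenes(a2$truth))
  expect_identical(truthRegions(a1$truth), truthRegions(a2$truth))
  t1 <- simulateInsertions(cfg, g1, a1$truth)
  t2 <- simulateInsertions(cfg, g2, a2$truth)
  expect_identical(tisPositions(t1), tisPositions(t2))
  expect_identical(tisCounts(t1), tisCounts(t2))
  # different seed -> different landscape
  cfgB <- smallSynthConfig(seed = 12)
  t3 <- simulateInsertions(cfgB, g1, generateAnnotation(cfgB, g1)$truth)
  expect_false(identical(tisPositions(t1), tisPositions(t3)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(genomeLength = -5), "positive")
  expect_error(synthConfig(gcFraction = 1.2), "proportions")
  expect_error(synthConfig(fractionEssential = 0.7,
                           fractionPseudogene = 0.5), "<= 1")
  expect_error(synthConfig(genomeLength = 1000, nInsertions = 2000),
               "unique")
  expect_error(GenomeModel("x", length = 0), "positive")
  # infeasible gene packing
  cfg <- synthConfig(genomeLength = 10000, nGenes = 50,
                     meanGeneLength = 900, nInsertions = 100)
  expect_error(generateAnnotation(cfg, generateGenome(cfg)), "packed")
})

test_that("annotation labels match configured fractions and never overlap", {
  cfg <- synthConfig(genomeLength = 200000, nGenes = 100,
                     meanGeneLength = 900, fractionEssential = 0.1,
                     fractionPseudogene = 0.05, nInsertions = 1000,
                     seed = 7)
  ann <- generateAnnotation(cfg, generateGenome(cfg))
  g <- truthGenes(ann$truth)
  expect_equal(nrow(g), 100)
  expect_equal(sum(g$class %in% c("essential",
                                  "essential_with_dispensable_domain")), 10)
  expect_equal(sum(g$class == "pseudogene"), 5)
  expect_equal(anyDuplicated(g$gene_id), 0)
  # pairwise interval check: genes sorted by start must not overlap
  o <- order(g$start)
  expect_true(all(g$start[o][-1] >= g$end[o][-nrow(g)]))
  # dispensable domains sit at the 3'-proximal 30% of their gene
  d <- g[g$class == "essential_with_dispensable_domain", ]
  expect_gt(nrow(d), 0)
  plus <- d$strand == "+"
  expect_true(all(d$domain_end[plus] == d$end[plus]))
  expect_true(all(d$domain_start[!plus] == d$start[!plus]))

  empty <- synthConfig(genomeLength = 10000, nGenes = 0, nInsertions = 10,
                       protectedRegionCount = 0)
  ann0 <- generateAnnotation(empty, generateGenome(empty))
  expect_equal(nrow(ann0$genes), 0)
  expect_equal(nrow(truthGenes(ann0$truth)), 0)
})

test_that("zero essential-core rate leaves essential cores insertion-free", {
  cfg <- smallSynthConfig(seed = 5, essentialBodyRateRatio = 0,
                          fractionEssentialWithDispensableDomain = 0)
  g <- generateGenome(cfg)
  ann <- generateAnnotation(cfg, g)
  tis <- simulateInsertions(cfg, g, ann$truth)
  tg <- truthGenes(ann$truth)
  ess <- tg[tg$class == "essential", ]
  pos <- tisPositions(tis)
  for (i in seq_len(nrow(ess))) {
    L <- ess$end[i] - ess$start[i]
    trim <- floor(0.04 * L)
    core <- pos >= ess$start[i] + trim & pos < ess$end[i] - trim
    expect_equal(sum(core), 0)
  }
})

test_that("protection ratio 1 leaves planted regions at background density", {
  cfg <- synthConfig(genomeLength = 500000, nGenes = 0,
                     nInsertions = 50000, protectedRegionCount = 20,
                     protectedRegionLength = 500, protectionRateRatio = 1,
                     seed = 9)
  g <- generateGenome(cfg)
  ann <- generateAnnotation(cfg, g)
  tis <- simulateInsertions(cfg, g, ann$truth)
  pr <- truthRegions(ann$truth)
  inReg <- sum(computeIpkm(pr$start, pr$end, tis)$nTis)
  protBp <- sum(pr$end - pr$start)
  bt <- binom.test(inReg, totalUnique(tis), p = protBp / 500000)
  expect_gt(bt$p.value, 0.01)
})

test_that("with all ratios 1 the landscape is uniform (chi-square GOF)", {
  cfg <- synthConfig(genomeLength = 500000, nGenes = 0, nInsertions = 50000,
                     protectedRegionCount = 0, seed = 2)
  g <- generateGenome(cfg)
  tis <- simulateInsertions(cfg, g, generateAnnotation(cfg, g)$truth)
  bins <- table(cut(tisPositions(tis), breaks = seq(0, 500000, by = 1000),
                    right = FALSE))
  expect_gt(chisq.test(as.vector(bins))$p.value, 0.001)
})

test_that("essential genes end up with lower ecIPKM than nonessential ones", {
  cfg <- smallSynthConfig(seed = 4)
  g <- generateGenome(cfg)
  ann <- generateAnnotation(cfg, g)
  tis <- simulateInsertions(cfg, g, ann$truth)
  st <- geneStats(ann$genes, tis)
  tg <- truthGenes(ann$truth)
  essMean <- mean(st$ec_ipkm[tg$class == "essential"])
  neMean <- mean(st$ec_ipkm[tg$class == "nonessential"])
  expect_lt(essMean, neMean)
  # pseudogenes behave like nonessential background
  expect_gt(mean(st$ec_ipkm[tg$class == "pseudogene"]), essMean)
})

test_that("config and ground truth round-trip through text files", {
  cfg <- smallSynthConfig(seed = 21, gcFraction = 0.42)
  path <- tempfile(fileext = ".yaml")
  writeSynthConfig(cfg, path)
  cfg2 <- readSynthConfig(path)
  for (f in methods::slotNames(cfg))
    expect_equal(methods::slot(cfg2, f), methods::slot(cfg, f), info = f)
  expect_error(readSynthConfig({
    p <- tempfile(); writeLines("bogus_key: 1", p); p
  }), "unknown keys")

  g <- generateGenome(cfg)
  ann <- generateAnnotation(cfg, g)
  tf <- tempfile(fileext = ".tsv")
  writeGroundTruth(ann$truth, tf)
  tab <- read.delim(tf)
  expect_equal(sum(tab$record == "gene"), nrow(truthGenes(ann$truth)))
  expect_equal(sum(tab$record == "protected"),
               nrow(truthRegions(ann$truth)))
})
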