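test_that("IPKM follows its closed form", {
  g <- toyGenome(100000)
  # 10 sites inside [0, 1000), 990 elsewhere -> totalUnique = 1000
  inside <- seq(50, 950, by = 100)
  outside <- seq(2000, by = 20, length.out = 990)   # all below 22,000
  tis <- TisTable(g, sort(c(inside, outside)))
  res <- computeIpkm(0, 1000, tis, endTrim = 0)
  expect_equal(res$nTis, 10)
  expect_equal(res$ipkm, 10 * 1e9 / (1000 * 1000))
  # no sites -> 0 for any trim
  expect_equal(computeIpkm(30000, 31000, tis, endTrim = 0)$ipkm, 0)
  expect_equal(computeIpkm(30000, 31000, tis, endTrim = 0.04)$ipkm, 0)
})

test_that("end curation trims floor(0.04*L) bp from each end", {
  g <- toyGenome(10000)
  # gene [100, 200), sites at offsets 1, 3, 50, 97
  tis <- TisTable(g, c(101, 103, 150, 197))
  res <- computeIpkm(100, 200, tis, endTrim = 0.04)
  expect_equal(res$nTis, 1)        # only offset 50 survives [4, 96)
  expect_equal(res$effLength, 92)
  expect_equal(res$ipkm, 1 * 1e9 / (92 * 4))
  # raw-length denominator mode
  raw <- computeIpkm(100, 200, tis, endTrim = 0.04, useTrimmedLength = FALSE)
  expect_equal(raw$ipkm, 1 * 1e9 / (100 * 4))
  # genes shorter than 1/endTrim bp are not trimmed: both end sites stay
  short <- computeIpkm(100, 120, tis, endTrim = 0.04)
  expect_equal(short$nTis, 2)
  # single-base features are still a 1-bp density
  one <- computeIpkm(150, 151, tis, endTrim = 0.04)
  expect_equal(one$nTis, 1)
  expect_equal(one$effLength, 1)
  expect_error(computeIpkm(0, 10, tis, endTrim = 0.5), "0.5")
})

test_that("ecIPKM with zero trim equals raw IPKM and ignores outside sites", {
  tis <- makeUniformTis(L = 50000, n = 5000, seed = 2)
  set.seed(3)
  starts <- sample.int(49000, 50)
  ends <- starts + sample(200:800, 50, replace = TRUE)
  zeroTrim <- computeIpkm(starts, ends, tis, endTrim = 0)$ipkm
  expect_identical(zeroTrim, computeIpkm(starts, ends, tis)$ipkm)
  # curated counts can never exceed raw counts
  st <- geneStats(data.frame(gene_id = sprintf("g%02d", 1:50),
                             start = starts, end = ends), tis)
  expect_true(all(st$n_tis_curated <= st$n_tis_raw))
  expect_true(all((st$ec_ipkm == 0) == (st$n_tis_curated == 0)))

  # perturbation: dropping a site outside the trimmed interval leaves
  # ecIPKM unchanged
  g <- toyGenome(10000)
  tis2 <- TisTable(g, c(101, 150, 197, 5000))
  before <- computeIpkm(100, 200, tis2, endTrim = 0.04)$ipkm * 4  # rescale
  tis3 <- TisTable(g, c(150, 5000))                # sites 101,197 removed
  after <- computeIpkm(100, 200, tis3, endTrim = 0.04)$ipkm * 2
  expect_equal(before, after)
})

test_that("insertion index is sites per bp and ranks like raw IPKM", {
  g <- toyGenome(100000)
  tis <- TisTable(g, sort(c(seq(50, 950, by = 100),
                            seq(2000, 90000, by = 100))))
  expect_equal(computeInsertionIndex(0, 1000, tis), 0.01)
  expect_equal(computeInsertionIndex(30000, 31000, tis),
               10 / 1000)
  expect_equal(computeInsertionIndex(95000, 96000, tis), 0)

  lt <- makeUniformTis(L = 100000, n = 8000, seed = 5)
  set.seed(6)
  s <- sample.int(95000, 200)
  e <- s + sample(300:2000, 200, replace = TRUE)
  ii <- computeInsertionIndex(s, e, lt)
  ipkm <- computeIpkm(s, e, lt, endTrim = 0)$ipkm
  expect_equal(cor(ii, ipkm, method = "spearman"), 1)
  expect_equal(ipkm, ii * 1e9 / totalUnique(lt))
})

test_that("interval counting agrees with a brute-force linear scan", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(1000:100000, 1)
    n <- sample(10:min(L, 3000), 1)
    tis <- makeUniformTis(L = L, n = n, seed = rep)
    pos <- tisPositions(tis)
    s <- sample.int(L, 50) - 1
    w <- sample.int(L, 50)
    e <- pmin(s + w, L)
    got <- computeIpkm(s, e, tis, endTrim = 0)$nTis
    want <- vapply(seq_along(s),
                   function(i) sum(pos >= s[i] & pos < e[i]), numeric(1))
    expect_equal(got, want)
  }
})

test_that("cutoff sweep reports exact confusion counts and ROC", {
  stats <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    ec_ipkm = c(rep(1, 5), rep(10, 15)))
  reference <- sprintf("g%02d", 1:5)
  curve <- sweepCutoffs(stats, reference, cutoffGrid = c(0.5, 5, 20))
  cv <- cutoffTable(curve)
  # perfect separation at cutoff 5
  expect_equal(cv$accuracy[cv$cutoff == 5], 1)
  expect_equal(cv$coverage[cv$cutoff == 5], 1)
  expect_equal(selectedCutoff(curve), 5)
  # cutoff below every value: nothing called
  expect_equal(cv$TP[1] + cv$FP[1], 0)
  expect_equal(cv$coverage[1], 0)
  expect_equal(cv$accuracy[1], 15 / 20)
  # identities at every cutoff
  expect_true(all(cv$TP + cv$FN == 5))
  expect_true(all(cv$TP + cv$FP + cv$TN + cv$FN == 20))
  # ROC monotone along the ascending grid
  expect_true(all(diff(cv$TPR) >= 0))
  expect_true(all(diff(cv$FPR) >= 0))
  expect_equal(rocAuc(curve), 1)
  expect_error(sweepCutoffs(stats, character(0)), "calibration")
})

test_that("essential calls use strict inequality and exclusions", {
  stats <- data.frame(
    gene_id = c("a", "b", "c", "d", "phantom"),
    essential = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    ec_ipkm = c(0, 2.2, 1.0, 50, 0))
  res <- callEssential(stats, cutoff = 2.2)
  st <- res$stats
  expect_false("phantom" %in% st$gene_id)
  expect_equal(st$call[st$gene_id == "a"], "essential")
  # a tie at exactly the cutoff is nonessential
  expect_equal(st$call[st$gene_id == "b"], "nonessential")
  s <- res$summary
  expect_equal(s@nCalledEssential, 2)
  expect_equal(s@truePositives, 1)
  expect_equal(s@falsePositives, 1)
  expect_equal(s@falseNegatives, 1)
  # a cutoff above the maximum calls everything: full coverage
  all_in <- callEssential(stats, cutoff = max(stats$ec_ipkm) + 1)
  expect_equal(all_in$summary@coveragePercent, 100)
  expect_error(callEssential(stats, cutoff = 0), "positive")
})

test_that("three-way call-set comparison enumerates the Venn partition", {
  res <- compareCallsets(c("a", "b", "c"), c("b", "c", "d"),
                         c("c", "d", "e"))
  expect_equal(res$partition[["A_only"]], 1)   # a
  expect_equal(res$partition[["AB_only"]], 1)  # b
  expect_equal(res$partition[["ABR"]], 1)      # c
  expect_equal(res$partition[["BR_only"]], 1)  # d
  expect_equal(res$partition[["R_only"]], 1)   # e
  expect_equal(res$partition[["AR_only"]], 0)
  expect_equal(res$partition[["B_only"]], 0)
  expect_equal(unname(res$coverage), c(1 / 3, 2 / 3))

  same <- compareCallsets(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(unname(same$partition), c(0, 0, 0, 0, 0, 0, 2))
  disj <- compareCallsets("a", "b", "c")
  expect_equal(sum(disj$partition[c("A_only", "B_only", "R_only")]), 3)
  # exclusions removed from every set before counting
  excl <- compareCallsets(c("a", "z"), c("b", "z"), c("c", "z"),
                          exclusions = "z")
  expect_equal(sum(excl$partition), 3)
})

test_that("group summaries report medians and drop empty groups", {
  stats <- data.frame(gene_id = c("a", "b", "c", "d"),
                      ec_ipkm = c(0, 1, 2, 9))
  expect_warning(
    sm <- summarizeDistributions(stats, list(abc = c("a", "b", "c"),
                                             solo = "d",
                                             none = "zz")),
    "empty")
  expect_equal(sm$median[sm$group == "abc"], 1)
  expect_equal(sm$median[sm$group == "solo"], 9)
  expect_false("none" %in% sm$group)
})

test_that("genes spanning the origin of a circular genome are counted", {
  g <- toyGenome(1000)
  tis <- TisTable(g, c(5, 990, 995))
  # gene [950, 1020) wraps: contains 990, 995, 5
  res <- computeIpkm(950, 1020, tis, endTrim = 0)
  expect_equal(res$nTis, 3)
  lin <- GenomeModel("lin", length = 1000, circular = FALSE)
  tisLin <- TisTable(lin, c(5, 990, 995))
  expect_equal(computeIpkm(950, 1020, tisLin, endTrim = 0)$nTis, 2)
})
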