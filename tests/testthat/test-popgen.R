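mkGt <- function(a, b, locus = "L") {
  data.frame(locus = locus, des_a = a, des_b = b, stringsAsFactors = FALSE)
}

test_that("allele frequencies count homozygotes twice", {
  g <- mkGt(rep("12", 10), rep("12", 10))
  expect_equal(alleleFrequencies(g), c("12" = 1))
  g <- mkGt(c("a", "a"), c("a", "b"))
  f <- alleleFrequencies(g)
  expect_equal(f[["a"]], 0.75)
  expect_equal(f[["b"]], 0.25)
  # single-record homozygotes count as two copies
  g <- data.frame(locus = "L", des_a = c("a", "a"), des_b = c(NA, "b"),
                  stringsAsFactors = FALSE)
  f <- alleleFrequencies(g)
  expect_equal(f[["a"]], 0.75)
  # incomplete genotypes are excluded with a warning
  g <- data.frame(locus = "L", des_a = c("a", NA), des_b = c("a", NA),
                  stringsAsFactors = FALSE)
  expect_warning(f <- alleleFrequencies(g), "incomplete")
  expect_equal(f[["a"]], 1)
})

test_that("sequence-level frequencies sum to their length class", {
  g <- data.frame(locus = "L",
                  des_a = c("8", "8", "8", "9"),
                  des_b = c("8", "8", "9", "9"),
                  seq_a = c("L:8", "L:8v", "L:8", "L:9"),
                  seq_b = c("L:8v", "L:8v", "L:9", "L:9"),
                  stringsAsFactors = FALSE)
  fLen <- alleleFrequencies(g, level = "length")
  fSeq <- alleleFrequencies(g, level = "sequence")
  expect_equal(fSeq[["L:8"]] + fSeq[["L:8v"]], fLen[["8"]])
  expect_equal(fSeq[["L:9"]], fLen[["9"]])
})

test_that("heterozygosities match a pairwise-draw oracle", {
  g <- mkGt(rep("12", 10), rep("12", 10))
  h <- heterozygosities(g)
  expect_equal(h$h_obs, 0)
  expect_equal(h$h_exp, 0)
  set.seed(14)
  g <- mkGt(sample(c("a", "b", "c"), 40, TRUE),
            sample(c("a", "b", "c"), 40, TRUE))
  h <- heterozygosities(g)
  expect_equal(h$h_obs, mean(g$des_a != g$des_b))
  # oracle: probability two chromosomes drawn without replacement differ
  chroms <- c(g$des_a, g$des_b)
  n2 <- length(chroms)
  diffs <- 0
  for (i in seq_len(n2 - 1)) for (j in (i + 1):n2)
    diffs <- diffs + (chroms[i] != chroms[j])
  expect_equal(h$h_exp, diffs / choose(n2, 2))
  # balanced biallelic locus approaches 0.5
  g <- mkGt(rep(c("a", "b"), 500), rep(c("b", "a"), 500))
  expect_equal(heterozygosities(g)$h_exp, 0.5, tolerance = 1e-3)
})

test_that("forensic parameters follow their defining formulas", {
  g <- mkGt(rep("12", 10), rep("12", 10))
  fp <- forensicParams(g)
  expect_equal(fp$mp, 1)
  expect_equal(fp$pd, 0)
  expect_equal(fp$pe, 0)
  # h_obs = 0.5 gives TPI 1
  g <- mkGt(c("a", "a", "a", "b"), c("b", "a", "b", "b"))
  fp <- forensicParams(g)
  expect_equal(fp$tpi, 1)
  # genotype-class oracle at {aa: 25, ab: 50, bb: 25}
  g <- mkGt(c(rep("a", 75), rep("b", 25)),
            c(rep("a", 25), rep("b", 75)))
  fp <- forensicParams(g)
  expect_equal(fp$mp, 0.25^2 + 0.5^2 + 0.25^2)
  expect_equal(fp$pd + fp$mp, 1)
  h <- 0.5
  H <- 0.5
  expect_equal(fp$pe, h^2 * (1 - 2 * h * H^2))
  # all-heterozygous locus leaves TPI undefined
  g <- mkGt(rep("a", 4), rep("b", 4))
  fp <- forensicParams(g)
  expect_true(fp$tpi_undefined)
  expect_equal(fp$tpi, Inf)
})

test_that("exact HWE enumeration matches a brute-force pairing oracle", {
  # two homozygotes, no heterozygote
  g <- mkGt(c("a", "b"), c("a", "b"))
  r <- hweExactTest(g, method = "enumerate")
  expect_equal(r$p, bruteForceHweP(g$des_a, g$des_b))
  # three genotypes, two alleles
  g <- mkGt(c("a", "a", "b"), c("a", "b", "b"))
  r <- hweExactTest(g, method = "enumerate")
  expect_equal(r$p, bruteForceHweP(g$des_a, g$des_b))
  # monomorphic convention
  expect_equal(hweExactTest(mkGt("a", "a"))$p, 1)
})

test_that("Monte-Carlo permutation converges to full enumeration", {
  set.seed(11)
  al <- sample(c("a", "b", "c"), 40, TRUE, prob = c(0.5, 0.3, 0.2))
  g <- mkGt(al[1:20], al[21:40])
  e <- hweExactTest(g, method = "enumerate")
  p <- hweExactTest(g, method = "permute", nPerm = 20000L, seed = 3L)
  se <- sqrt(e$p * (1 - e$p) / 20000)
  expect_lt(abs(p$p - e$p), 3 * se)
  expect_error(hweExactTest(g, method = "permute"), "seed")
})

test_that("HWE-consistent cohorts are not rejected", {
  sp <- simpleSpectrum("D2S441", c(10, 11, 12), c(0.5, 0.3, 0.2))
  cfg <- oneLocusConfig(sp, nSamples = 500L, seed = 29L)
  g <- generatePopulation(cfg)
  gt <- data.frame(locus = "D2S441", des_a = g$des_a, des_b = g$des_b,
                   stringsAsFactors = FALSE)
  r <- hweExactTest(gt, method = "permute", nPerm = 10000L, seed = 5L)
  expect_gt(r$p, 0.05)
})

test_that("cohort frequencies converge to configured spectra", {
  sp <- simpleSpectrum("D2S441", c(9, 10, 11, 12), c(0.4, 0.3, 0.2, 0.1))
  cfg <- oneLocusConfig(sp, nSamples = 5000L, seed = 37L)
  g <- generatePopulation(cfg)
  f <- alleleFrequencies(data.frame(locus = "D2S441", des_a = g$des_a,
                                    des_b = g$des_b,
                                    stringsAsFactors = FALSE))
  for (i in seq_len(nrow(sp))) {
    des <- as.character(sp$units[i])
    tol <- 3 * sqrt(sp$freq[i] * (1 - sp$freq[i]) / (2 * 5000))
    expect_lt(abs(f[[des]] - sp$freq[i]), tol)
  }
})

test_that("heterozygosity gain reports the isoallele bookkeeping", {
  iso <- buildScenario("isoallele_1075")
  hg <- heterozygosityGain(iso$genotypes)
  b <- hg$by_locus
  # structural identity per locus
  expect_equal(b$total_alleles_sequence,
               b$total_alleles_length + b$isoalleles)
  expect_true(all(b$h_obs_sequence >= b$h_obs_length))
  # a locus without isoalleles keeps identical columns
  fga <- b[b$locus == "D18S51", ]
  expect_equal(fga$isoalleles, 0L)
  expect_equal(fga$total_alleles_length, fga$total_alleles_sequence)
  expect_equal(fga$h_obs_length, fga$h_obs_sequence)
})

test_that("per-locus summaries keep pd and mp complementary", {
  cfg <- defaultSimulationConfig(theCatalog, nSamples = 50L, seed = 41L)
  g <- generatePopulation(cfg)
  gt <- data.frame(locus = g$locus, des_a = g$des_a, des_b = g$des_b,
                   seq_a = g$seq_a, seq_b = g$seq_b, stringsAsFactors = FALSE)
  ps <- locusPopStats(gt, hweSeed = 2L, hweNPerm = 2000L)
  expect_equal(ps$pd + ps$mp, rep(1, nrow(ps)))
  expect_true(all(ps$hwe_p >= 0 & ps$hwe_p <= 1))
  expect_equal(ps$hom_exp, 1 - ps$h_exp)
  # sequence level never shows less heterozygosity than length level
  seqStats <- locusPopStats(gt, hweSeed = 2L, hweNPerm = 500L,
                            level = "sequence")
  expect_true(all(seqStats$h_obs >= ps$h_obs))
})
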