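test_that("degenerate spectra and seeds behave deterministically", {
  sp <- simpleSpectrum("D2S441", 10, 1)
  cfg <- oneLocusConfig(sp, nSamples = 25L, seed = 3L)
  g <- generatePopulation(cfg)
  expect_true(all(g$seq_a == "D2S441:10" & g$seq_b == "D2S441:10"))
  # identical config gives bit-identical cohorts and reads
  g2 <- generatePopulation(cfg)
  expect_identical(g, g2)
  expect_identical(profileReads(simulateReads(g, cfg)),
                   profileReads(simulateReads(g2, cfg)))
  expect_error(oneLocusConfig(simpleSpectrum("D2S441", 10, 0.9)),
               "sum to 1")
})

test_that("heterozygote fraction follows Hardy-Weinberg proportions", {
  sp <- simpleSpectrum("D2S441", c(10, 12), c(0.5, 0.5))
  cfg <- oneLocusConfig(sp, nSamples = 10000L, seed = 11L)
  g <- generatePopulation(cfg)
  hetFrac <- mean(g$seq_a != g$seq_b)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(hetFrac - 0.5), 3 * se)
})

test_that("degenerate balance model gives both alleles equal reads", {
  sp <- simpleSpectrum("D2S441", c(10, 12), c(0.5, 0.5))
  cfg <- oneLocusConfig(sp, nSamples = 60L, seed = 4L, hbShape2 = 0)
  g <- generatePopulation(cfg)
  pr <- profileReads(simulateReads(g, cfg))
  het <- g[g$seq_a != g$seq_b, ]
  for (i in seq_len(nrow(het))) {
    ra <- pr$reads[pr$sample_id == het$sample_id[i] &
                   pr$sequence_id == het$seq_a[i]]
    rb <- pr$reads[pr$sample_id == het$sample_id[i] &
                   pr$sequence_id == het$seq_b[i]]
    expect_equal(ra, rb)
  }
})

test_that("per-sample reads are conserved across allele and stutter rows", {
  cfg <- defaultSimulationConfig(theCatalog, nSamples = 20L, seed = 9L)
  g <- generatePopulation(cfg)
  pr <- simulateReads(g, cfg)
  rd <- profileReads(pr)
  expect_equal(as.numeric(totalReads(pr)),
               as.numeric(tapply(rd$reads, rd$sample_id,
                                 sum)[sampleIds(pr)]))
  expect_true(all(rd$reads >= 1))
})

test_that("mean stutter ratio grows with repeat count", {
  sp <- simpleSpectrum("D18S51", c(11, 20), c(0.5, 0.5))
  cfg <- oneLocusConfig(sp, locus = "D18S51", nSamples = 2500L, seed = 21L)
  g <- generatePopulation(cfg)
  pr <- simulateReads(g, cfg)
  calls <- callGenotypes(applyAnalyticalThreshold(pr, 50), theCatalog)
  rec <- stutterRatios(pr, calls)
  mShort <- mean(rec$ratio[rec$parent_designation == "11"])
  mLong <- mean(rec$ratio[rec$parent_designation == "20"])
  expect_gt(mLong, mShort)
  # misconfigured model with mean ratio >= 1 is rejected
  bad <- oneLocusConfig(sp, locus = "D18S51", nSamples = 5L, seed = 1L,
                        stutterIntercept = 1.2)
  expect_error(simulateReads(generatePopulation(bad), bad),
               "misconfiguration")
})

test_that("simulated cohorts recover configured stutter means", {
  cfg <- defaultSimulationConfig(theCatalog, nSamples = 150L, seed = 33L)
  g <- generatePopulation(cfg)
  pr <- simulateReads(g, cfg)
  calls <- callGenotypes(applyAnalyticalThreshold(pr, 50), theCatalog)
  rec <- stutterRatios(pr, calls)
  expect_gt(nrow(rec), 5000)   # enough parent alleles for recovery
  par <- parseDesignation(rec$parent_designation)
  sp <- cfg@stutterParams
  i <- match(rec$locus, sp$locus)
  configured <- sp$intercept[i] + sp$slope[i] * par$units
  configured[par$partial > 0L] <- configured[par$partial > 0L] * 0.7
  for (locus in unique(rec$locus)) {
    sel <- rec$locus == locus
    expect_lt(abs(mean(rec$ratio[sel]) - mean(configured[sel])), 0.01)
  }
})

test_that("injected drop-out and drop-in events appear in the read table", {
  cfg <- defaultSimulationConfig(theCatalog, nSamples = 10L, seed = 13L)
  g <- generatePopulation(cfg)
  target <- g[g$locus == "D2S1338" & g$seq_a != g$seq_b, ][1L, ]
  cfg@dropout <- data.frame(sample_id = target$sample_id,
                            locus = "D2S1338", which = "longer",
                            stringsAsFactors = FALSE)
  cfg@dropin <- data.frame(sample_id = "S0001", locus = "TPOX",
                           sequence_id = "TPOX:11:dropin", units = 11L,
                           partial = 0L, reads = 373L,
                           stringsAsFactors = FALSE)
  pr <- profileReads(simulateReads(g, cfg))
  longer <- if (compareDesignation(target$des_a, target$des_b) > 0)
    target$seq_a else target$seq_b
  expect_false(any(pr$sample_id == target$sample_id &
                   pr$sequence_id == longer))
  din <- pr[pr$sequence_id == "TPOX:11:dropin", ]
  expect_equal(din$reads, 373L)
  # the spurious sequence survives the analytical threshold
  f <- applyAnalyticalThreshold(simulateReads(g, cfg), 50)
  expect_true("TPOX:11:dropin" %in% profileReads(f)$sequence_id)
})

test_that("ground-truth CE tables render designation multisets", {
  sp <- rbind(simpleSpectrum("D2S1338", c(18, 28), c(0.5, 0.5), iso = TRUE))
  cfg <- oneLocusConfig(sp, locus = "D2S1338", nSamples = 50L, seed = 17L)
  g <- generatePopulation(cfg)
  ce <- deriveCeDataset(g, cfg, theCatalog)
  i <- which(g$seq_a == "D2S1338:18" & g$seq_b == "D2S1338:28")
  expect_true(length(i) > 0)
  expect_equal(unique(ce$allele1[i]), "18")
  expect_equal(unique(ce$allele2[i]), "28")
  # isometric heterozygote renders as a repeated single designation
  j <- which(g$seq_a == "D2S1338:18" & g$seq_b == "D2S1338:18:v1")
  expect_true(length(j) > 0)
  expect_equal(unique(ce$allele1[j]), "18")
  expect_equal(unique(ce$allele2[j]), "18")
  # empty cohort gives an empty table
  expect_equal(nrow(deriveCeDataset(g[0, ], cfg, theCatalog)), 0L)
})

test_that("unknown scenario names list the available builders", {
  expect_error(buildScenario("nope"), "concordance_247")
})
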