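mkProfiles <- function(reads, sequences) {
  new("ReadProfileSet", reads = reads, sequences = sequences)
}

seqAnn <- function(ids, locus, units, partial = 0L) {
  data.frame(sequence_id = ids, locus = locus, units = as.integer(units),
             partial = as.integer(rep_len(partial, length(ids))),
             variant_ids = "", stringsAsFactors = FALSE)
}

test_that("analytical threshold retention is inclusive at the boundary", {
  rd <- data.frame(sample_id = "s1", locus = "TPOX",
                   sequence_id = c("TPOX:8", "TPOX:9", "TPOX:11"),
                   reads = c(49L, 50L, 373L), stringsAsFactors = FALSE)
  pr <- mkProfiles(rd, seqAnn(c("TPOX:8", "TPOX:9", "TPOX:11"), "TPOX",
                              c(8, 9, 11)))
  f <- applyAnalyticalThreshold(pr, 50)
  expect_setequal(profileReads(f)$sequence_id, c("TPOX:9", "TPOX:11"))
  expect_equal(attr(f, "n_removed"), 1L)
  # at = 0 is the identity
  f0 <- applyAnalyticalThreshold(pr, 0)
  expect_equal(nrow(profileReads(f0)), 3L)
  # raising the threshold never retains more sequences
  kept <- vapply(c(0, 10, 50, 100, 400, 1000), function(at)
    nrow(profileReads(applyAnalyticalThreshold(pr, at))), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("interpretation thresholds decide the genotype call", {
  ann <- seqAnn(c("D2S1338:18", "D2S1338:28", "TPOX:11", "vWA:15", "vWA:16",
                  "FGA:20", "FGA:21", "FGA:22"),
                c("D2S1338", "D2S1338", "TPOX", "vWA", "vWA",
                  "FGA", "FGA", "FGA"),
                c(18, 28, 11, 15, 16, 20, 21, 22))
  rd <- data.frame(
    sample_id = "s1",
    locus = c("D2S1338", "TPOX", "vWA", "vWA", "FGA", "FGA", "FGA"),
    sequence_id = c("D2S1338:18", "TPOX:11", "vWA:15", "vWA:16",
                    "FGA:20", "FGA:21", "FGA:22"),
    reads = c(1750L, 373L, 120L, 110L, 900L, 800L, 700L),
    stringsAsFactors = FALSE)
  calls <- genotypeCalls(callGenotypes(mkProfiles(rd, ann), theCatalog))
  d2 <- calls[calls$locus == "D2S1338", ]
  expect_true(d2$homozygous)
  expect_equal(d2$des_a, "18")
  expect_true(is.na(d2$seq_b))
  # single candidate between the thresholds: flagged, not forced homozygous
  tp <- calls[calls$locus == "TPOX", ]
  expect_true(is.na(tp$seq_a))
  expect_match(tp$flags, "possible_dropout")
  expect_match(tp$flags, "no_call")
  # two candidates at or above the heterozygous threshold
  vw <- calls[calls$locus == "vWA", ]
  expect_false(vw$homozygous)
  expect_setequal(c(vw$des_a, vw$des_b), c("15", "16"))
  # three strong candidates: triallelic pattern is not called
  fg <- calls[calls$locus == "FGA", ]
  expect_match(fg$flags, "triallelic")
  expect_true(is.na(fg$seq_a))
})

test_that("stutter-position sequences are not treated as candidates", {
  ann <- seqAnn(c("vWA:17", "vWA:16:stut", "vWA:16"), "vWA", c(17, 16, 16))
  # lone parent with a strong stutter: stutter filtered, homozygous call
  rd <- data.frame(sample_id = "s1", locus = "vWA",
                   sequence_id = c("vWA:17", "vWA:16:stut"),
                   reads = c(2000L, 260L), stringsAsFactors = FALSE)
  calls <- genotypeCalls(callGenotypes(mkProfiles(rd, ann), theCatalog))
  expect_true(calls$homozygous)
  expect_equal(calls$des_a, "17")
  # an adjacent true allele has a high ratio and is kept
  rd2 <- data.frame(sample_id = "s1", locus = "vWA",
                    sequence_id = c("vWA:17", "vWA:16"),
                    reads = c(2000L, 1700L), stringsAsFactors = FALSE)
  calls2 <- genotypeCalls(callGenotypes(mkProfiles(rd2, ann), theCatalog))
  expect_false(calls2$homozygous)
  expect_setequal(c(calls2$des_a, calls2$des_b), c("17", "16"))
})

test_that("calls are invariant to the ordering of input sequences", {
  ann <- seqAnn(c("vWA:15", "vWA:16"), "vWA", c(15, 16))
  rd <- data.frame(sample_id = "s1", locus = "vWA",
                   sequence_id = c("vWA:15", "vWA:16"),
                   reads = c(800L, 900L), stringsAsFactors = FALSE)
  a <- genotypeCalls(callGenotypes(mkProfiles(rd, ann), theCatalog))
  b <- genotypeCalls(callGenotypes(mkProfiles(rd[2:1, ], ann), theCatalog))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("run classification follows the recommended bands", {
  rm <- readRunMetrics(system.file("extdata", "run_metrics.tsv",
                                   package = "strmps"))
  cls <- vapply(seq_len(nrow(rm)), function(i)
    classifyRun(rm[i, ])$density_class, "")
  expect_equal(cls, c("under", "over", "optimal", "over", "under"))
  expect_true(all(vapply(seq_len(nrow(rm)), function(i)
    classifyRun(rm[i, ])$q30_pass, NA)))
  expect_error(classifyRun(list(cluster_density_mean = -5, pct_q30 = 80)),
               "non-negative")
})

test_that("run Q30 summary reports mean and sample SD to one decimal", {
  rm <- readRunMetrics(system.file("extdata", "run_metrics.tsv",
                                   package = "strmps"))
  s <- summarizeRuns(rm)
  expect_equal(s$mean, 83.2)
  expect_equal(s$sd, 4.1)
  expect_equal(summarizeRuns(data.frame(pct_q30 = c(80, 80)))$sd, 0)
  expect_error(summarizeRuns(data.frame(pct_q30 = 80)), "two runs")
  # agrees with a direct two-pass variance oracle
  set.seed(5)
  x <- round(runif(5, 70, 95), 1)
  m <- mean(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  s <- summarizeRuns(data.frame(pct_q30 = x))
  expect_equal(s$mean, floor(m * 10 + 0.5) / 10)
  expect_equal(s$sd, floor(sqrt(v) * 10 + 0.5) / 10)
})
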