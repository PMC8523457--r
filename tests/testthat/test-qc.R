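test_that("relative marker performance is the per-marker read share", {
  markers <- loci(theCatalog)$name
  rd <- data.frame(sample_id = "s1", locus = markers,
                   sequence_id = paste0(markers, ":x"),
                   reads = 1000L, stringsAsFactors = FALSE)
  ann <- data.frame(sequence_id = rd$sequence_id, locus = markers,
                    units = NA_integer_, partial = NA_integer_,
                    variant_ids = "", stringsAsFactors = FALSE)
  pr <- new("ReadProfileSet", reads = rd, sequences = ann)
  rmp <- relativeMarkerPerformance(pr)
  expect_equal(rmp$fraction, rep(1 / 23, 23))
  # a single non-zero marker takes the full share
  rd2 <- rd
  rd2$reads <- c(500L, rep(0L, 22))
  pr2 <- new("ReadProfileSet", reads = rd2, sequences = ann)
  rmp2 <- relativeMarkerPerformance(pr2)
  expect_equal(sort(rmp2$fraction, decreasing = TRUE)[1], 1)
  expect_equal(sum(rmp2$fraction), 1)
  # random profile: fractions match a per-marker sum / grand sum oracle
  set.seed(31)
  rd3 <- rd
  rd3$reads <- as.integer(sample(100:5000, 23))
  pr3 <- new("ReadProfileSet", reads = rd3, sequences = ann)
  rmp3 <- relativeMarkerPerformance(pr3)
  oracle <- tapply(rd3$reads, rd3$locus, sum) / sum(rd3$reads)
  expect_equal(rmp3$fraction, as.numeric(oracle[rmp3$locus]))
  expect_equal(sum(rmp3$fraction), 1, tolerance = 1e-12)
})

test_that("expected marker share is 100 over the marker count", {
  expect_equal(expectedRMP(23), 4.35)
  expect_equal(expectedRMP(1), 100)
  expect_equal(expectedRMP(4), 25)
  expect_error(expectedRMP(0), ">= 1")
})

test_that("markers outside mean plus/minus one SD of marker means flag", {
  even <- setNames(rep(4.35, 23), paste0("M", 1:23))
  expect_length(flagUnbalancedMarkers(even)$flagged, 0L)
  one <- even
  one["M7"] <- 9
  expect_equal(flagUnbalancedMarkers(one)$flagged, "M7")
  # constructed profile with eight markers pushed outside the band
  set.seed(12)
  mm <- setNames(rep(4.35, 23), paste0("M", 1:23))
  out <- paste0("M", c(1, 4, 7, 10, 12, 15, 19, 23))
  mm[out] <- 4.35 + c(2.2, -1.9, 2.5, -2.1, 1.9, -2.3, 2.0, -2.4)
  fl <- flagUnbalancedMarkers(mm)
  expect_setequal(fl$flagged, out)
})

test_that("heterozygote balance is a symmetric scale-free minor/major ratio", {
  expect_equal(heterozygoteBalance(100, 100)$hb, 1)
  hb <- heterozygoteBalance(30, 100)
  expect_equal(hb$hb, 0.30)
  expect_true(hb$imbalanced)
  expect_equal(heterozygoteBalance(721, 1000)$hb, 0.721)
  expect_false(heterozygoteBalance(721, 1000)$imbalanced)
  expect_error(heterozygoteBalance(0, 100), "drop-out")
  set.seed(8)
  a <- sample(100:5000, 20)
  b <- sample(100:5000, 20)
  expect_equal(heterozygoteBalance(a, b)$hb, heterozygoteBalance(b, a)$hb)
  expect_equal(heterozygoteBalance(7 * a, 7 * b)$hb,
               heterozygoteBalance(a, b)$hb)
})

test_that("read-depth categories use inclusive boundaries", {
  expect_equal(categorizeSample(63500), "I")
  expect_equal(categorizeSample(199000), "II")
  expect_equal(categorizeSample(100000), "none")
  expect_equal(categorizeSample(c(1000, 250000)), c("I", "II"))
  expect_error(categorizeSample(5, low = 10, high = 10), "below")
})

test_that("stutter ratios divide the n-1 length class by the parent", {
  ann <- data.frame(
    sequence_id = c("vWA:16", "vWA:15:stut", "vWA:15", "vWA:14:stut"),
    locus = "vWA", units = c(16L, 15L, 15L, 14L), partial = 0L,
    variant_ids = "", stringsAsFactors = FALSE)
  # lone homozygous parent with one stutter class
  rd <- data.frame(sample_id = "s1", locus = "vWA",
                   sequence_id = c("vWA:16", "vWA:15:stut"),
                   reads = c(1000L, 120L), stringsAsFactors = FALSE)
  pr <- new("ReadProfileSet", reads = rd, sequences = ann)
  calls <- callGenotypes(pr, theCatalog)
  rec <- stutterRatios(pr, calls)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ratio, 0.12)
  expect_equal(rec$parent_designation, "16")
  # adjacent heterozygote: the 16 parent is skipped, only 15 contributes
  rd2 <- data.frame(sample_id = "s1", locus = "vWA",
                    sequence_id = c("vWA:16", "vWA:15", "vWA:14:stut"),
                    reads = c(1000L, 950L, 95L), stringsAsFactors = FALSE)
  pr2 <- new("ReadProfileSet", reads = rd2, sequences = ann)
  calls2 <- callGenotypes(pr2, theCatalog)
  rec2 <- stutterRatios(pr2, calls2)
  expect_equal(rec2$parent_designation, "15")
  expect_equal(rec2$ratio, 95 / 950)
})

test_that("stutter summaries match a direct sort/quantile oracle", {
  set.seed(77)
  recs <- data.frame(
    sample_id = sprintf("s%02d", 1:40), locus = "D18S51",
    parent_designation = "14", parent_reads = 1000L,
    stutter_reads = as.integer(round(runif(40, 50, 260))),
    category = rep(c("I", "II"), each = 20), stringsAsFactors = FALSE)
  recs$ratio <- recs$stutter_reads / recs$parent_reads
  s <- summarizeStutter(recs)
  for (cat in c("I", "II")) {
    r <- recs$ratio[recs$category == cat]
    row <- s[s$category == cat, ]
    expect_equal(row$n, 20L)
    expect_equal(row$mean, mean(r))
    expect_equal(row$sd, sd(r))
    expect_equal(row$median, median(r))
    expect_equal(row$min, min(r))
    expect_equal(row$max, max(r))
    expect_equal(row$n_above_threshold, sum(r > 0.20))
  }
  # a single observation reports no SD
  one <- recs[1L, ]
  s1 <- summarizeStutter(one)
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$min, s1$max)
  expect_true(is.na(s1$sd))
  # ratios all at 0.10 never exceed the 20 percent flag
  recs$ratio <- 0.10
  expect_equal(sum(summarizeStutter(recs)$n_above_threshold), 0L)
})
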