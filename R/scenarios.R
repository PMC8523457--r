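#' @title Deterministic worked-example scenarios
#' @description Scenario builders that reproduce, exactly and from a fixed
#'   internal seed, cohorts with known aggregate properties: a 247-sample
#'   concordance study with two injected single-allele drop-outs, an
#'   isometric-allele reclassification cohort, a heterozygote-balance
#'   flagging cohort, and a D19S433 intermediate-allele cohort.
#' @name scenarios
NULL

.scenarioNames <- c("concordance_247", "isoallele_1075", "hb_flags_5434",
                    "d19_intermediate_494")

.scenarioConcordance247 <- function() {
  catalog <- defaultCatalog()
  config <- defaultSimulationConfig(catalog, nSamples = 247L, seed = 46L)
  # tight read model so every locus call clears the interpretation
  # thresholds and the only discordances are the two injected events
  config@readsMeanlog <- log(150000)
  config@readsSdlog <- 0.2
  config@hbShape1 <- 90
  config@hbShape2 <- 10
  # declare the long D2S1338 allele used by the drop-out case
  sp <- config@spectra[["D2S1338"]]
  sp <- rbind(sp, data.frame(sequence_id = "D2S1338:28", units = 28L,
                             partial = 0L, variant_ids = "", freq = 0,
                             stringsAsFactors = FALSE))
  config@spectra[["D2S1338"]] <- sp
  validObject(config)
  g <- generatePopulation(config)
  fix <- function(g, sample, locus, seqs, des) {
    i <- which(g$sample_id == sample & g$locus == locus)
    g$seq_a[i] <- seqs[1L]; g$seq_b[i] <- seqs[2L]
    g$des_a[i] <- des[1L]; g$des_b[i] <- des[2L]
    g
  }
  g <- fix(g, "S0001", "D2S1338", c("D2S1338:18", "D2S1338:28"),
           c("18", "28"))
  g <- fix(g, "S0002", "PentaE", c("PentaE:8", "PentaE:11"), c("8", "11"))
  config@dropout <- data.frame(
    sample_id = c("S0001", "S0002"), locus = c("D2S1338", "PentaE"),
    which = c("longer", "shorter"), stringsAsFactors = FALSE)
  profiles <- simulateReads(g, config)
  ce <- deriveCeDataset(g, config, catalog)
  list(name = "concordance_247", catalog = catalog, config = config,
       genotypes = g, profiles = profiles, ce = ce)
}

.scenarioIsoallele1075 <- function() {
  isoCounts <- c(D5S818 = 34L, D3S1358 = 25L, D13S317 = 23L, D21S11 = 16L,
                 D7S820 = 15L, D8S1179 = 14L, D16S539 = 14L, vWA = 11L,
                 D2S1338 = 9L, D2S441 = 8L, D12S391 = 6L, D1S1656 = 4L,
                 TPOX = 2L)
  loci <- .locusDefaults$locus
  homTotal <- 1075L
  homPlain <- homTotal - sum(isoCounts)       # 894 untouched homozygotes
  base <- rep(homPlain %/% length(loci), length(loci))
  extra <- homPlain %% length(loci)
  base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  names(base) <- loci
  rows <- list()
  sid <- 0L
  mkRows <- function(locus, n, iso) {
    if (n < 1L) return(NULL)
    u <- .locusDefaults$lo[.locusDefaults$locus == locus] + 2L
    des <- as.character(u)
    seqA <- paste0(locus, ":", u)
    seqB <- if (iso) paste0(locus, ":", u, ":v1") else NA_character_
    data.frame(sample_id = sprintf("H%04d", sid + seq_len(n)), locus = locus,
               seq_a = seqA, seq_b = seqB, des_a = des,
               des_b = if (iso) des else NA_character_,
               stringsAsFactors = FALSE)
  }
  for (locus in loci) {
    r <- mkRows(locus, base[[locus]], iso = FALSE)
    rows <- c(rows, list(r))
    sid <- sid + base[[locus]]
    niso <- if (locus %in% names(isoCounts)) isoCounts[[locus]] else 0L
    if (niso > 0L) {
      r <- mkRows(locus, niso, iso = TRUE)
      rows <- c(rows, list(r))
      sid <- sid + niso
    }
    # a few ordinary length heterozygotes so all three classes occur
    u <- .locusDefaults$lo[.locusDefaults$locus == locus] + 2L
    het <- data.frame(sample_id = sprintf("H%04d", sid + 1:5), locus = locus,
                      seq_a = paste0(locus, ":", u),
                      seq_b = paste0(locus, ":", u + 1L),
                      des_a = as.character(u), des_b = as.character(u + 1L),
                      stringsAsFactors = FALSE)
    rows <- c(rows, list(het))
    sid <- sid + 5L
  }
  genotypes <- do.call(rbind, rows)
  rownames(genotypes) <- NULL
  list(name = "isoallele_1075", genotypes = genotypes)
}

.scenarioHbFlags5434 <- function() {
  loci <- .locusDefaults$locus
  samples <- sprintf("S%04d", seq_len(247L))
  grid <- expand.grid(sample_id = samples, locus = loci,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$locus), , drop = FALSE]
  u <- .locusDefaults$lo[match(grid$locus, .locusDefaults$locus)] + 2L
  calls <- data.frame(
    sample_id = grid$sample_id, locus = grid$locus,
    seq_a = paste0(grid$locus, ":", u),
    seq_b = paste0(grid$locus, ":", u + 1L),
    reads_a = 2000L, reads_b = 1700L,
    des_a = as.character(u), des_b = as.character(u + 1L),
    homozygous = FALSE, flags = "", stringsAsFactors = FALSE)
  # seven highly imbalanced calls: five at D2S1338, one each at D19S433
  # and D21S11
  imb <- rbind(
    data.frame(sample_id = sprintf("S%04d", 1:5), locus = "D2S1338"),
    data.frame(sample_id = "S0006", locus = "D19S433"),
    data.frame(sample_id = "S0007", locus = "D21S11"))
  for (j in seq_len(nrow(imb))) {
    i <- which(calls$sample_id == imb$sample_id[j] &
               calls$locus == imb$locus[j])
    calls$reads_b[i] <- 500L   # HB = 0.25
  }
  rownames(calls) <- NULL
  list(name = "hb_flags_5434", calls = new("GenotypeCallSet", calls = calls))
}

.scenarioD19Intermediate494 <- function() {
  nSamples <- 247L
  nCarrier <- 55L
  samples <- sprintf("S%04d", seq_len(nSamples))
  carrier <- seq_len(nCarrier)
  genotypes <- data.frame(
    sample_id = samples, locus = "D19S433",
    seq_a = ifelse(seq_len(nSamples) %in% carrier,
                   "D19S433:12.3:del", "D19S433:13"),
    seq_b = "D19S433:14",
    des_a = ifelse(seq_len(nSamples) %in% carrier, "12.3", "13"),
    des_b = "14",
    var_a = ifelse(seq_len(nSamples) %in% carrier, "rs147936416", ""),
    var_b = "", stringsAsFactors = FALSE)
  list(name = "d19_intermediate_494", genotypes = genotypes)
}

#' Build a named deterministic scenario
#'
#' Available scenarios: \code{"concordance_247"} (247 samples x 22 loci with
#' exactly two injected single-allele drop-outs), \code{"isoallele_1075"}
#' (1075 length-homozygous genotypes of which 181 are isometric
#' heterozygotes), \code{"hb_flags_5434"} (5434 locus calls with seven
#' highly imbalanced heterozygotes), \code{"d19_intermediate_494"} (494
#' D19S433 alleles of which 55 carry the rs147936416 deletion).
#'
#' @param name scenario identifier.
#' @return A list of scenario datasets; components depend on the scenario
#'   (see each builder's description).
#' @export
buildScenario <- function(name) {
  if (!name %in% .scenarioNames)
    stop("unknown scenario '", name, "'; available: ",
         paste(.scenarioNames, collapse = ", "))
  switch(name,
         concordance_247 = .scenarioConcordance247(),
         isoallele_1075 = .scenarioIsoallele1075(),
         hb_flags_5434 = .scenarioHbFlags5434(),
         d19_intermediate_494 = .scenarioD19Intermediate494())
}

#' Carrier rate of a catalogued variant among alleles
#'
#' Counts alleles (two per complete genotype) whose carried-variant
#' annotation includes the given id.
#'
#' @param genotypes genotype data.frame with columns \code{var_a},
#'   \code{var_b} (comma-separated carried variant ids).
#' @param variantId catalogue variant id.
#' @return List: \code{n_alleles}, \code{n_carriers}, \code{pct} (one
#'   decimal).
#' @export
variantCarrierRate <- function(genotypes, variantId) {
  carries <- function(x) vapply(strsplit(ifelse(is.na(x), "", x), ","),
                                function(v) variantId %in% trimws(v), NA)
  vb <- ifelse(is.na(genotypes$seq_b), genotypes$var_a, genotypes$var_b)
  nAll <- 2L * nrow(genotypes)
  nCar <- sum(carries(genotypes$var_a)) + sum(carries(vb))
  list(n_alleles = nAll, n_carriers = nCar,
       pct = roundHalfUp(100 * nCar / nAll, 1))
}
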