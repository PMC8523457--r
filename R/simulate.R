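#' @title Synthetic cohort simulation
#' @description Generates paired MPS read-count and CE genotype datasets with
#'   the statistical structure the downstream analyses assume: diploid
#'   genotypes drawn under Hardy-Weinberg proportions from per-locus allele
#'   spectra, log-normal per-sample totals shared out by marker weights,
#'   Beta-distributed heterozygote balance, one-repeat-shorter stutter whose
#'   mean ratio grows with repeat count, and explicit drop-out/drop-in
#'   injection.
#' @name simulate
NULL

#' Simulation configuration
#'
#' @slot nSamples integer cohort size.
#' @slot spectra named list (per STR locus) of data.frames with columns
#'   \code{sequence_id}, \code{units}, \code{partial}, \code{variant_ids},
#'   \code{freq}; frequencies sum to 1 per locus (zero-frequency entries are
#'   allowed to declare sequences used only by injected events).
#' @slot readsMeanlog,readsSdlog log-normal parameters of per-sample total
#'   reads.
#' @slot markerWeights named numeric, expected read share per marker
#'   (amelogenin included); sums to 1.
#' @slot hbShape1,hbShape2 Beta parameters of heterozygote balance
#'   (\code{hbShape2 = 0} declares the degenerate model with HB exactly 1).
#' @slot stutterParams data.frame(\code{locus}, \code{intercept},
#'   \code{slope}, \code{sd}): mean stutter ratio of a parent with u repeat
#'   units is \code{intercept + slope * u}, noise is Gaussian with
#'   \code{sd}, truncated at 0.
#' @slot intermediateFactor multiplier on the mean stutter ratio of
#'   intermediate (partial-repeat) parents (< 1: intermediates stutter less).
#' @slot dropout data.frame(\code{sample_id}, \code{locus}, \code{which})
#'   with \code{which} in \{"shorter", "longer"\}: injected allele drop-outs.
#' @slot dropin data.frame(\code{sample_id}, \code{locus},
#'   \code{sequence_id}, \code{units}, \code{partial}, \code{reads}):
#'   injected spurious sequences.
#' @slot seed integer; all randomness flows from it via per-stage sub-seeds.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSamples = "integer", spectra = "list",
                 readsMeanlog = "numeric", readsSdlog = "numeric",
                 markerWeights = "numeric",
                 hbShape1 = "numeric", hbShape2 = "numeric",
                 stutterParams = "data.frame",
                 intermediateFactor = "numeric",
                 dropout = "data.frame", dropin = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@seed) != 1L || is.na(object@seed))
      return("a single integer seed is mandatory")
    if (object@nSamples < 1L) return("nSamples must be >= 1")
    for (nm in names(object@spectra)) {
      sp <- object@spectra[[nm]]
      if (!all(c("sequence_id", "units", "partial", "variant_ids", "freq")
               %in% names(sp)))
        return(paste("spectrum of", nm, "lacks required columns"))
      if (!nrow(sp)) return(paste("empty spectrum at", nm))
      if (abs(sum(sp$freq) - 1) > 1e-9)
        return(paste("frequencies at", nm, "do not sum to 1"))
      if (any(sp$freq < 0)) return(paste("negative frequency at", nm))
      if (anyDuplicated(sp$sequence_id))
        return(paste("duplicate sequence_id in spectrum of", nm))
    }
    if (abs(sum(object@markerWeights) - 1) > 1e-9)
      return("marker weights must sum to 1")
    num <- c(object@readsMeanlog, object@readsSdlog, object@hbShape1,
             object@hbShape2, object@intermediateFactor,
             object@stutterParams$intercept, object@stutterParams$slope,
             object@stutterParams$sd)
    if (!all(is.finite(num))) return("all model parameters must be finite")
    TRUE
  })

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,",
      length(object@spectra), "STR loci, seed", object@seed, "\n")
})

# mean stutter ratio for parents at a locus with given units/partial
.stutterMean <- function(config, locus, units, partial) {
  sp <- config@stutterParams
  i <- match(locus, sp$locus)
  m <- sp$intercept[i] + sp$slope[i] * units
  ifelse(partial > 0L, m * config@intermediateFactor, m)
}

# default per-locus allele unit ranges and target mean stutter ratios;
# chosen once as typical for these markers, declared in the vignette
.locusDefaults <- data.frame(
  locus = c("D1S1656", "TPOX", "D2S1338", "D2S441", "D3S1358", "FGA",
            "D5S818", "CSF1PO", "D7S820", "D8S1179", "D10S1248", "TH01",
            "vWA", "D12S391", "D13S317", "PentaE", "D16S539", "D18S51",
            "D19S433", "D21S11", "PentaD", "D22S1045"),
  lo = c(11, 6, 16, 9, 13, 18, 8, 8, 7, 9, 11, 5, 13, 16, 8, 7, 8, 11, 11,
         26, 6, 10),
  hi = c(17, 12, 25, 14, 19, 26, 13, 13, 13, 16, 17, 10, 20, 24, 14, 18,
         14, 20, 16, 33, 15, 17),
  stutter_mean = c(0.14, 0.055, 0.13, 0.06, 0.12, 0.12, 0.09, 0.08, 0.085,
                   0.105, 0.13, 0.055, 0.12, 0.12, 0.07, 0.065, 0.105,
                   0.125, 0.13, 0.095, 0.03, 0.15),
  stringsAsFactors = FALSE)

# loci where the default spectra split the modal length class into an
# isometric pair (repeat-region SNP variant of identical length)
.isoSplitLoci <- c("D5S818", "D3S1358", "D13S317", "D21S11", "D7S820",
                   "D8S1179", "D16S539", "vWA", "D2S1338", "D2S441",
                   "D12S391", "D1S1656", "TPOX")

#' Default simulation configuration
#'
#' Per-locus allele spectra over typical unit ranges with triangular
#' frequency profiles; isometric splits of the modal length class at the 13
#' loci where sequence variation resolves extra alleles; a D2S441 flanking
#' deletion carrier (rs888232687) and a D19S433 intermediate-allele carrier
#' (rs147936416) at low frequency; equal marker weights for the 23-marker
#' panel; log-normal totals around 120k reads; Beta(24, 4) heterozygote
#' balance; per-locus stutter means between 3 and 15 percent growing with
#' repeat count.
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param nSamples cohort size (default 200).
#' @param seed mandatory integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
defaultSimulationConfig <- function(catalog, nSamples = 200L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  ld <- .locusDefaults
  ld <- ld[ld$locus %in% strLocusNames(catalog), , drop = FALSE]
  spectra <- list()
  for (i in seq_len(nrow(ld))) {
    locus <- ld$locus[i]
    units <- seq(ld$lo[i], ld$hi[i])
    w <- pmin(seq_along(units), rev(seq_along(units)))
    sp <- data.frame(
      sequence_id = paste0(locus, ":", units),
      units = units, partial = 0L, variant_ids = "",
      freq = w / sum(w), stringsAsFactors = FALSE)
    if (locus %in% .isoSplitLoci) {
      m <- which.max(sp$freq)
      iso <- sp[m, , drop = FALSE]
      iso$sequence_id <- paste0(iso$sequence_id, ":v1")
      iso$freq <- 0.3 * sp$freq[m]
      sp$freq[m] <- 0.7 * sp$freq[m]
      sp <- rbind(sp, iso)
    }
    if (locus == "D2S441") {
      carrier <- data.frame(sequence_id = "D2S441:10:del", units = 10L,
                            partial = 0L, variant_ids = "rs888232687",
                            freq = 0.02, stringsAsFactors = FALSE)
      sp$freq <- sp$freq * 0.98
      sp <- rbind(sp, carrier)
    }
    if (locus == "D19S433") {
      carrier <- data.frame(sequence_id = "D19S433:12.3:del", units = 12L,
                            partial = 3L, variant_ids = "rs147936416",
                            freq = 0.05, stringsAsFactors = FALSE)
      sp$freq <- sp$freq * 0.95
      sp <- rbind(sp, carrier)
    }
    spectra[[locus]] <- sp
  }
  markers <- catalog@loci$name
  weights <- setNames(rep(1 / length(markers), length(markers)), markers)
  mid <- (ld$lo + ld$hi) / 2
  stutterParams <- data.frame(
    locus = ld$locus,
    intercept = ld$stutter_mean - 0.009 * mid,
    slope = 0.009, sd = 0.02, stringsAsFactors = FALSE)
  new("SimulationConfig",
      nSamples = as.integer(nSamples), spectra = spectra,
      readsMeanlog = log(120000), readsSdlog = 0.5,
      markerWeights = weights, hbShape1 = 24, hbShape2 = 4,
      stutterParams = stutterParams, intermediateFactor = 0.7,
      dropout = data.frame(sample_id = character(), locus = character(),
                           which = character(), stringsAsFactors = FALSE),
      dropin = data.frame(sample_id = character(), locus = character(),
                          sequence_id = character(), units = integer(),
                          partial = integer(), reads = integer(),
                          stringsAsFactors = FALSE),
      seed = as.integer(seed))
}

#' Sequence annotation table of a configuration
#'
#' All sequences the configuration can emit (spectrum alleles, their
#' one-repeat-shorter stutter classes, injected drop-ins, amelogenin), in
#' the annotation format of \linkS4class{ReadProfileSet}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame(\code{sequence_id}, \code{locus}, \code{units},
#'   \code{partial}, \code{variant_ids}).
#' @export
spectrumAnnotation <- function(config) {
  base <- do.call(rbind, lapply(names(config@spectra), function(locus) {
    sp <- config@spectra[[locus]]
    data.frame(sequence_id = sp$sequence_id, locus = locus,
               units = sp$units, partial = sp$partial,
               variant_ids = sp$variant_ids, stringsAsFactors = FALSE)
  }))
  stut <- base
  stut$sequence_id <- paste0(stut$sequence_id, ":stut")
  stut$units <- stut$units - 1L
  stut <- stut[stut$units >= 1L, , drop = FALSE]
  amel <- data.frame(sequence_id = "AMEL:XY", locus = "AMEL",
                     units = NA_integer_, partial = NA_integer_,
                     variant_ids = "", stringsAsFactors = FALSE)
  din <- config@dropin
  dinAnn <- if (nrow(din))
    data.frame(sequence_id = din$sequence_id, locus = din$locus,
               units = din$units, partial = din$partial, variant_ids = "",
               stringsAsFactors = FALSE)
  else NULL
  ann <- rbind(base, stut, amel, dinAnn)
  ann[!duplicated(ann$sequence_id), , drop = FALSE]
}

#' Draw a diploid cohort under Hardy-Weinberg proportions
#'
#' Genotypes are drawn independently per locus: each allele is an
#' independent draw from the locus spectrum, so genotype classes follow
#' p squared / 2pq. Reproducible given the configuration seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame of true genotypes: \code{sample_id}, \code{locus},
#'   \code{seq_a}, \code{seq_b}, \code{des_a}, \code{des_b} (repeat-count
#'   designations; \code{seq_a <= seq_b} lexicographically for determinism).
#' @export
generatePopulation <- function(config) {
  set.seed(config@seed)
  samples <- sprintf("S%04d", seq_len(config@nSamples))
  out <- vector("list", length(config@spectra))
  for (k in seq_along(config@spectra)) {
    locus <- names(config@spectra)[k]
    sp <- config@spectra[[locus]]
    ia <- sample.int(nrow(sp), config@nSamples, replace = TRUE, prob = sp$freq)
    ib <- sample.int(nrow(sp), config@nSamples, replace = TRUE, prob = sp$freq)
    swap <- sp$sequence_id[ia] > sp$sequence_id[ib]
    tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
    out[[k]] <- data.frame(
      sample_id = samples, locus = locus,
      seq_a = sp$sequence_id[ia], seq_b = sp$sequence_id[ib],
      des_a = formatDesignation(sp$units[ia], sp$partial[ia]),
      des_b = formatDesignation(sp$units[ib], sp$partial[ib]),
      stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  g[order(g$sample_id, g$locus), , drop = FALSE]
}

#' Simulate sequence read counts for a cohort
#'
#' Each sample draws a log-normal total; each marker receives its weight
#' share; heterozygote reads split as minor share HB/(1+HB) with a fair coin
#' deciding the minor allele; every parent allele emits a one-repeat-shorter
#' stutter sequence with ratio drawn around the locus stutter mean
#' (truncated at 0); injected drop-outs zero an allele's reads (and its
#' stutter), injected drop-ins add spurious sequences. Read counts are
#' integers (nearest, ties to even) so thresholding is exact.
#'
#' @param genotypes output of \code{\link{generatePopulation}} (possibly
#'   edited, as the deterministic scenario builders do).
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ReadProfileSet}.
#' @export
simulateReads <- function(genotypes, config) {
  set.seed(config@seed + 1L)
  ann <- spectrumAnnotation(config)
  samples <- unique(genotypes$sample_id)
  totals <- round(rlnorm(length(samples), config@readsMeanlog,
                         config@readsSdlog))
  names(totals) <- samples
  g <- genotypes
  w <- config@markerWeights
  locusReads <- as.numeric(totals[g$sample_id]) * as.numeric(w[g$locus])
  het <- g$seq_a != g$seq_b
  # hbShape2 = 0 declares the degenerate balance model: HB identically 1
  hb <- if (config@hbShape2 == 0) rep(1, nrow(g)) else
    rbeta(nrow(g), config@hbShape1, config@hbShape2)
  minorShare <- hb / (1 + hb)
  minorIsA <- runif(nrow(g)) < 0.5
  shareA <- ifelse(het, ifelse(minorIsA, minorShare, 1 - minorShare), 1)
  readsA <- round(locusReads * shareA)
  readsB <- ifelse(het, round(locusReads * (1 - shareA)), 0)
  # stutter ratios per parent allele
  ua <- ann$units[match(g$seq_a, ann$sequence_id)]
  pa <- ann$partial[match(g$seq_a, ann$sequence_id)]
  ub <- ann$units[match(g$seq_b, ann$sequence_id)]
  pb <- ann$partial[match(g$seq_b, ann$sequence_id)]
  mA <- .stutterMean(config, g$locus, ua, pa)
  mB <- .stutterMean(config, g$locus, ub, pb)
  if (any(c(mA, mB) >= 1))
    stop("stutter model misconfiguration: mean ratio >= 1")
  ratioA <- pmax(0, mA + rnorm(nrow(g), 0, config@stutterParams$sd[
    match(g$locus, config@stutterParams$locus)]))
  ratioB <- pmax(0, mB + rnorm(nrow(g), 0, config@stutterParams$sd[
    match(g$locus, config@stutterParams$locus)]))
  stutA <- ifelse(ua >= 2L, round(readsA * ratioA), 0)
  stutB <- ifelse(het & ub >= 2L, round(readsB * ratioB), 0)
  mkRows <- function(idx, seqs, reads) {
    if (!length(idx)) return(NULL)
    data.frame(sample_id = g$sample_id[idx], locus = g$locus[idx],
               sequence_id = seqs, reads = reads[idx],
               stringsAsFactors = FALSE)
  }
  allIdx <- seq_len(nrow(g))
  hetIdx <- which(het)
  rows <- do.call(rbind, list(
    mkRows(allIdx, g$seq_a, readsA),
    mkRows(hetIdx, g$seq_b[hetIdx], readsB),
    mkRows(allIdx, paste0(g$seq_a, ":stut"), stutA),
    mkRows(hetIdx, paste0(g$seq_b[hetIdx], ":stut"), stutB)))
  # same length class from two parents (adjacent or isometric alleles) can
  # emit the same stutter sequence id twice: merge
  keyAgg <- paste(rows$sample_id, rows$locus, rows$sequence_id, sep = "\r")
  if (anyDuplicated(keyAgg)) {
    reads <- tapply(rows$reads, keyAgg, sum)
    first <- !duplicated(keyAgg)
    rows <- rows[first, , drop = FALSE]
    rows$reads <- as.numeric(reads[paste(rows$sample_id, rows$locus,
                                         rows$sequence_id, sep = "\r")])
  }
  # amelogenin share
  if ("AMEL" %in% names(w))
    rows <- rbind(rows, data.frame(
      sample_id = samples, locus = "AMEL", sequence_id = "AMEL:XY",
      reads = round(as.numeric(totals) * w[["AMEL"]]),
      stringsAsFactors = FALSE))
  # injected drop-outs: zero the targeted allele and its stutter
  dq <- config@dropout
  for (j in seq_len(nrow(dq))) {
    gi <- which(g$sample_id == dq$sample_id[j] & g$locus == dq$locus[j])
    if (!length(gi)) stop("dropout event targets absent genotype")
    gi <- gi[1L]
    cmp <- compareDesignation(g$des_a[gi], g$des_b[gi])
    target <- if (dq$which[j] == "longer") {
      if (cmp >= 0) g$seq_a[gi] else g$seq_b[gi]
    } else {
      if (cmp <= 0) g$seq_a[gi] else g$seq_b[gi]
    }
    drop <- rows$sample_id == dq$sample_id[j] & rows$locus == dq$locus[j] &
      rows$sequence_id %in% c(target, paste0(target, ":stut"))
    rows <- rows[!drop, , drop = FALSE]
  }
  # injected drop-ins
  din <- config@dropin
  if (nrow(din))
    rows <- rbind(rows, data.frame(
      sample_id = din$sample_id, locus = din$locus,
      sequence_id = din$sequence_id, reads = din$reads,
      stringsAsFactors = FALSE))
  rows <- rows[rows$reads > 0, , drop = FALSE]
  rows$reads <- as.integer(rows$reads)
  rows <- rows[order(rows$sample_id, rows$locus, rows$sequence_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  new("ReadProfileSet", reads = rows,
      sequences = ann[ann$sequence_id %in% rows$sequence_id, , drop = FALSE])
}

#' Ground-truth CE genotype table of a cohort
#'
#' Per sample and locus, the multiset of CE-equivalent designations of the
#' true alleles (homozygotes as a single repeated designation), as a CE
#' workflow would report them.
#'
#' @param genotypes output of \code{\link{generatePopulation}}.
#' @param config the \linkS4class{SimulationConfig} that produced them.
#' @param catalog a \linkS4class{StrCatalog}.
#' @return data.frame(\code{sample_id}, \code{locus}, \code{allele1},
#'   \code{allele2}), alleles ordered by designation value.
#' @export
deriveCeDataset <- function(genotypes, config, catalog) {
  if (!nrow(genotypes))
    return(data.frame(sample_id = character(), locus = character(),
                      allele1 = character(), allele2 = character(),
                      stringsAsFactors = FALSE))
  ann <- spectrumAnnotation(config)
  ia <- match(genotypes$seq_a, ann$sequence_id)
  ib <- match(genotypes$seq_b, ann$sequence_id)
  ceA <- ceDesignationString(catalog, genotypes$locus, ann$units[ia],
                             ann$partial[ia], ann$variant_ids[ia])
  ceB <- ceDesignationString(catalog, genotypes$locus, ann$units[ib],
                             ann$partial[ib], ann$variant_ids[ib])
  swap <- compareDesignation(ceA, ceB) > 0L
  a1 <- ifelse(swap, ceB, ceA)
  a2 <- ifelse(swap, ceA, ceB)
  data.frame(sample_id = genotypes$sample_id, locus = genotypes$locus,
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}
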