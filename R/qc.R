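#' @title Profile-level quality control
#' @description Relative marker performance, heterozygote balance and
#'   length-defined (univariate) stutter ratios with read-depth categories.
#' @name qc
NULL

#' Relative marker performance per profile
#'
#' For each sample, the fraction of that profile's total reads carried by
#' each marker (amelogenin included). Fractions of one profile sum to 1.
#'
#' @param profiles a \linkS4class{ReadProfileSet}.
#' @return data.frame with columns \code{sample_id}, \code{locus},
#'   \code{fraction}.
#' @export
relativeMarkerPerformance <- function(profiles) {
  rd <- profiles@reads
  tot <- tapply(rd$reads, rd$sample_id, sum)
  if (any(tot == 0))
    stop("profile with zero total reads: ",
         paste(names(tot)[tot == 0], collapse = ", "))
  agg <- aggregate(reads ~ sample_id + locus, data = rd, FUN = sum)
  agg$fraction <- agg$reads / as.numeric(tot[agg$sample_id])
  agg[order(agg$sample_id, agg$locus), c("sample_id", "locus", "fraction")]
}

#' Expected relative marker performance
#'
#' Under equal marker performance every one of \code{nMarkers} markers would
#' receive the same share of reads.
#'
#' @param nMarkers number of markers in the panel (amelogenin included).
#' @return Expected share in percent, two decimals (4.35 for 23 markers).
#' @export
expectedRMP <- function(nMarkers) {
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  roundHalfUp(100 / nMarkers, 2)
}

#' Flag markers outside the well-balanced band
#'
#' The band is defined as the grand mean of the per-marker mean relative
#' performances plus/minus one SD of those marker means.
#'
#' @param markerMeans named numeric vector of per-marker mean relative
#'   performance (fractions or percent; the band is scale-free).
#' @return List with \code{flagged} (marker names outside the band),
#'   \code{band} (lower/upper), \code{sd_marker_means}.
#' @export
flagUnbalancedMarkers <- function(markerMeans) {
  if (length(markerMeans) < 2L)
    stop("need at least two markers")
  gm <- mean(markerMeans)
  s <- sd(markerMeans)
  band <- c(lower = gm - s, upper = gm + s)
  flagged <- names(markerMeans)[markerMeans < band[["lower"]] |
                                markerMeans > band[["upper"]]]
  list(flagged = flagged, band = band, sd_marker_means = s)
}

#' Heterozygote balance
#'
#' Ratio of the minor to the major allele read count of a heterozygous call;
#' symmetric in its arguments, scale invariant, in (0, 1]. Calls at or below
#' the flag threshold (default 0.30) are marked imbalanced.
#'
#' @param readsA,readsB read counts of the two alleles (vectorised).
#' @param flagThreshold HB at or below which the call is flagged.
#' @return data.frame with columns \code{hb} and \code{imbalanced}.
#' @export
heterozygoteBalance <- function(readsA, readsB, flagThreshold = 0.30) {
  if (any(readsA <= 0 | readsB <= 0))
    stop("heterozygote balance needs positive reads on both alleles ",
         "(zero reads is drop-out territory)")
  hb <- pmin(readsA, readsB) / pmax(readsA, readsB)
  data.frame(hb = hb, imbalanced = hb <= flagThreshold)
}

#' Heterozygote balance of every heterozygous call
#'
#' @param calls a \linkS4class{GenotypeCallSet}.
#' @param flagThreshold HB at or below which a call is flagged (default 0.30).
#' @return data.frame with \code{sample_id}, \code{locus}, \code{hb},
#'   \code{imbalanced}, plus attributes \code{n_flagged} and
#'   \code{flagged_pct} (percentage of all locus calls, two decimals).
#' @export
profileHeterozygoteBalance <- function(calls, flagThreshold = 0.30) {
  cl <- calls@calls
  het <- cl[!cl$homozygous & !is.na(cl$seq_a) & !is.na(cl$seq_b), ,
            drop = FALSE]
  out <- data.frame(sample_id = het$sample_id, locus = het$locus)
  hb <- heterozygoteBalance(het$reads_a, het$reads_b, flagThreshold)
  out$hb <- hb$hb
  out$imbalanced <- hb$imbalanced
  attr(out, "n_flagged") <- sum(out$imbalanced)
  attr(out, "flagged_pct") <- roundHalfUp(100 * sum(out$imbalanced) /
                                          nrow(cl), 2)
  out
}

#' Read-depth category of a sample
#'
#' Samples are grouped by profile total reads: category I at or below
#' \code{low}, category II at or above \code{high}, otherwise none. The
#' boundaries are inclusive.
#'
#' @param total profile total reads (vectorised).
#' @param low category-I ceiling (default 63500 reads).
#' @param high category-II floor (default 199000 reads).
#' @return Character vector in \{"I", "II", "none"\}.
#' @export
categorizeSample <- function(total, low = 63500, high = 199000) {
  if (low >= high) stop("low threshold must be below high threshold")
  ifelse(total <= low, "I", ifelse(total >= high, "II", "none"))
}

#' Stutter ratios of called alleles
#'
#' Stutter is considered length-defined and univariate: the stutter position
#' of a parent allele is one full repeat unit shorter (same partial). The
#' ratio is the summed reads at that length class divided by the parent
#' reads. Parents whose stutter position coincides with the genotype's other
#' allele are skipped to avoid allele-inflated ratios.
#'
#' @param profiles a \linkS4class{ReadProfileSet} (unfiltered or
#'   AT-filtered; stutter reads below AT simply yield ratio 0 contributions
#'   that are absent).
#' @param calls a \linkS4class{GenotypeCallSet}.
#' @param low,high read-depth category bounds (see
#'   \code{\link{categorizeSample}}).
#' @return data.frame of stutter records: \code{sample_id}, \code{locus},
#'   \code{parent_designation}, \code{parent_reads}, \code{stutter_reads},
#'   \code{ratio}, \code{category}.
#' @export
stutterRatios <- function(profiles, calls, low = 63500, high = 199000) {
  rd <- profiles@reads
  sq <- profiles@sequences
  i <- match(rd$sequence_id, sq$sequence_id)
  rd$units <- sq$units[i]
  rd$partial <- sq$partial[i]
  tot <- tapply(rd$reads, rd$sample_id, sum)
  cl <- calls@calls
  cl <- cl[!is.na(cl$seq_a), , drop = FALSE]
  if (!nrow(cl)) return(NULL)
  # one row per called parent allele
  par <- rbind(
    data.frame(sample_id = cl$sample_id, locus = cl$locus, seq = cl$seq_a,
               other = cl$seq_b, stringsAsFactors = FALSE),
    data.frame(sample_id = cl$sample_id[!cl$homozygous],
               locus = cl$locus[!cl$homozygous],
               seq = cl$seq_b[!cl$homozygous],
               other = cl$seq_a[!cl$homozygous], stringsAsFactors = FALSE))
  par <- par[!is.na(par$seq), , drop = FALSE]
  j <- match(par$seq, sq$sequence_id)
  par$units <- sq$units[j]
  par$partial <- sq$partial[j]
  oth <- match(par$other, sq$sequence_id)
  # skip parents whose one-repeat-shorter position is the other true allele
  overlap <- !is.na(oth) & sq$units[oth] == par$units - 1L &
    sq$partial[oth] == par$partial
  par <- par[!overlap & !is.na(par$units), , drop = FALSE]
  readKey <- paste(rd$sample_id, rd$locus, rd$sequence_id, sep = "\r")
  par$parent_reads <- rd$reads[match(
    paste(par$sample_id, par$locus, par$seq, sep = "\r"), readKey)]
  par <- par[!is.na(par$parent_reads) & par$parent_reads > 0, , drop = FALSE]
  # stutter reads: everything in the parent's n-1 length class except
  # called allele sequences themselves
  calledKey <- c(paste(cl$sample_id, cl$locus, cl$seq_a, sep = "\r"),
                 paste(cl$sample_id[!is.na(cl$seq_b)],
                       cl$locus[!is.na(cl$seq_b)],
                       cl$seq_b[!is.na(cl$seq_b)], sep = "\r"))
  isAllele <- readKey %in% calledKey
  clsKey <- paste(rd$sample_id, rd$locus, rd$units, rd$partial, sep = "\r")
  stutByClass <- tapply(rd$reads[!isAllele], clsKey[!isAllele], sum)
  want <- paste(par$sample_id, par$locus, par$units - 1L, par$partial,
                sep = "\r")
  sr <- as.numeric(stutByClass[want])
  sr[is.na(sr)] <- 0
  data.frame(
    sample_id = par$sample_id, locus = par$locus,
    parent_designation = formatDesignation(par$units, par$partial),
    parent_reads = par$parent_reads, stutter_reads = as.integer(sr),
    ratio = sr / par$parent_reads,
    category = categorizeSample(as.numeric(tot[par$sample_id]), low, high),
    stringsAsFactors = FALSE)
}

#' Summarise stutter ratios per locus and read-depth category
#'
#' @param records stutter record data.frame from \code{\link{stutterRatios}}.
#' @param flagThreshold ratio above which a stutter is counted as excessive
#'   (strictly greater; default 0.20).
#' @return data.frame per locus and category: \code{n}, \code{mean},
#'   \code{sd} (NA for single observations), \code{median}, \code{min},
#'   \code{max}, \code{n_above_threshold}.
#' @export
summarizeStutter <- function(records, flagThreshold = 0.20) {
  if (is.null(records) || !nrow(records))
    return(data.frame(locus = character(), category = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      median = numeric(), min = numeric(), max = numeric(),
                      n_above_threshold = integer()))
  sp <- split(records, list(records$locus, records$category), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    locus = d$locus[1L], category = d$category[1L], n = nrow(d),
    mean = mean(d$ratio),
    sd = if (nrow(d) > 1L) sd(d$ratio) else NA_real_,
    median = median(d$ratio), min = min(d$ratio), max = max(d$ratio),
    n_above_threshold = sum(d$ratio > flagThreshold))))
  rownames(out) <- NULL
  out[order(out$locus, out$category), , drop = FALSE]
}
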