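#' @title Threshold-based genotype calling and run QC
#' @description Applies the analytical threshold (AT) and interpretation
#'   thresholds (IT) to sequence read counts to produce genotype calls, and
#'   classifies sequencer run metrics against recommended bands.
#' @name calling
NULL

#' Apply the analytical threshold
#'
#' Sequences with fewer reads than \code{at} are removed before any
#' interpretation; retention is inclusive (reads >= at are kept). With
#' \code{at = 0} this is the identity.
#'
#' @param profiles a \linkS4class{ReadProfileSet}.
#' @param at analytical threshold in reads (default 50).
#' @return A filtered \linkS4class{ReadProfileSet}; the number of removed
#'   sequences is attached as attribute \code{"n_removed"}.
#' @export
applyAnalyticalThreshold <- function(profiles, at = 50) {
  if (at < 0) stop("analytical threshold must be >= 0")
  rd <- profiles@reads
  keep <- rd$reads >= at
  out <- new("ReadProfileSet", reads = rd[keep, , drop = FALSE],
             sequences = profiles@sequences)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Mark sequences that sit one full repeat unit below a stronger sequence of
# the same locus with a read ratio <= stutterFilter: these are treated as
# stutter artifacts, not allele candidates.
.markStutter <- function(d, stutterFilter) {
  n <- nrow(d)
  isStutter <- logical(n)
  if (n < 2L) return(isStutter)
  for (i in seq_len(n)) {
    parent <- d$units == d$units[i] + 1L & d$partial == d$partial[i] &
      d$reads > d$reads[i]
    if (any(parent) && d$reads[i] / max(d$reads[parent]) <= stutterFilter)
      isStutter[i] <- TRUE
  }
  isStutter
}

.callOne <- function(d, itHom, itHet, stutterFilter) {
  flags <- character()
  if (nrow(d)) {
    d <- d[order(-d$reads, d$sequence_id), , drop = FALSE]
    d <- d[!.markStutter(d, stutterFilter), , drop = FALSE]
  }
  strong <- d[d$reads >= itHet, , drop = FALSE]
  res <- list(seq_a = NA_character_, seq_b = NA_character_,
              reads_a = NA_integer_, reads_b = NA_integer_,
              homozygous = FALSE)
  if (nrow(strong) > 2L) {
    flags <- c("triallelic", "no_call")
  } else if (nrow(strong) == 2L) {
    res$seq_a <- strong$sequence_id[1L]
    res$seq_b <- strong$sequence_id[2L]
    res$reads_a <- as.integer(strong$reads[1L])
    res$reads_b <- as.integer(strong$reads[2L])
  } else if (nrow(strong) == 1L) {
    if (strong$reads[1L] >= itHom) {
      res$seq_a <- strong$sequence_id[1L]
      res$reads_a <- as.integer(strong$reads[1L])
      res$homozygous <- TRUE
    } else {
      flags <- c("possible_dropout", "no_call")
    }
  } else {
    flags <- "no_call"
  }
  res$flags <- paste(flags, collapse = ",")
  res
}

#' Call genotypes from thresholded read counts
#'
#' Per sample and STR locus, allele candidates are the non-stutter sequences
#' that survived the analytical threshold. Two candidates at or above
#' \code{itHet} give a heterozygous call; a single candidate at or above
#' \code{itHom} a homozygous call (one allele record plus the homozygous
#' marker); a single candidate between the thresholds is left uncalled with a
#' possible-dropout flag rather than forced homozygous; more than two strong
#' candidates are flagged triallelic and not called.
#'
#' @param profiles a \linkS4class{ReadProfileSet}, analytical threshold
#'   already applied (see \code{\link{applyAnalyticalThreshold}}).
#' @param catalog a \linkS4class{StrCatalog}.
#' @param itHom interpretation threshold for homozygous calls (default 500).
#' @param itHet interpretation threshold for heterozygous calls (default 100).
#' @param stutterFilter read-ratio ceiling below which a one-repeat-shorter
#'   sequence is treated as stutter (default 0.35).
#' @return A \linkS4class{GenotypeCallSet} with repeat-count designations.
#' @export
callGenotypes <- function(profiles, catalog, itHom = 500, itHet = 100,
                          stutterFilter = 0.35) {
  rd <- profiles@reads
  sq <- profiles@sequences
  strLoci <- strLocusNames(catalog)
  rd <- rd[rd$locus %in% strLoci, , drop = FALSE]
  i <- match(rd$sequence_id, sq$sequence_id)
  if (anyNA(i))
    stop("read table contains sequences missing from the annotation: ",
         paste(head(unique(rd$sequence_id[is.na(i)])), collapse = ", "))
  rd$units <- sq$units[i]
  rd$partial <- sq$partial[i]
  samples <- unique(rd$sample_id)
  grid <- expand.grid(sample_id = samples,
                      locus = intersect(strLoci, unique(rd$locus)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- split(seq_len(nrow(rd)), paste(rd$sample_id, rd$locus, sep = "\r"))
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    idx <- key[[paste(grid$sample_id[j], grid$locus[j], sep = "\r")]]
    .callOne(rd[idx, , drop = FALSE], itHom, itHet, stutterFilter)
  })
  calls <- data.frame(
    sample_id = grid$sample_id, locus = grid$locus,
    seq_a = vapply(rows, `[[`, "", "seq_a"),
    seq_b = vapply(rows, `[[`, "", "seq_b"),
    reads_a = vapply(rows, `[[`, NA_integer_, "reads_a"),
    reads_b = vapply(rows, `[[`, NA_integer_, "reads_b"),
    homozygous = vapply(rows, `[[`, NA, "homozygous"),
    flags = vapply(rows, `[[`, "", "flags"),
    stringsAsFactors = FALSE)
  ia <- match(calls$seq_a, sq$sequence_id)
  ib <- match(calls$seq_b, sq$sequence_id)
  calls$des_a <- ifelse(is.na(ia), NA_character_,
                        formatDesignation(sq$units[ia], sq$partial[ia]))
  calls$des_b <- ifelse(is.na(ib), NA_character_,
                        formatDesignation(sq$units[ib], sq$partial[ib]))
  calls <- calls[, c("sample_id", "locus", "seq_a", "seq_b", "reads_a",
                     "reads_b", "des_a", "des_b", "homozygous", "flags")]
  new("GenotypeCallSet", calls = calls)
}

#' Classify a sequencing run against recommended metric bands
#'
#' Cluster density is classed under (< 1000 K/mm2), optimal (1000-1200) or
#' over (> 1200); the Q30 criterion passes above 75 percent.
#'
#' @param metrics one-row data.frame (or list) of run metrics with fields
#'   \code{cluster_density_mean} and \code{pct_q30}.
#' @return List with \code{density_class} and \code{q30_pass}.
#' @export
classifyRun <- function(metrics) {
  d <- metrics$cluster_density_mean
  if (is.null(d) || is.na(d) || d < 0)
    stop("cluster density must be a non-negative number")
  cls <- if (d < 1000) "under" else if (d <= 1200) "optimal" else "over"
  list(run_id = if (!is.null(metrics$run_id)) metrics$run_id else NA_character_,
       density_class = cls,
       q30_pass = metrics$pct_q30 > 75)
}

#' Summarise Q30 quality across runs
#'
#' @param metrics data.frame of run metrics with column \code{pct_q30},
#'   one row per run.
#' @return List with \code{mean} and sample (n-1) \code{sd} of the percent of
#'   bases at or above Q30, both rounded to one decimal for reporting.
#' @export
summarizeRuns <- function(metrics) {
  q <- metrics$pct_q30
  if (length(q) < 2L)
    stop("at least two runs are needed for an SD")
  list(mean = roundHalfUp(mean(q), 1), sd = roundHalfUp(sd(q), 1))
}

#' Read a run-metrics table
#'
#' @param path TSV with one row per run (columns \code{run_id},
#'   \code{cluster_density_mean}, \code{cluster_density_sd}, \code{pct_pf},
#'   \code{phasing}, \code{prephasing}, \code{total_reads}, \code{reads_pf},
#'   \code{pct_q30}, ...). The package ships the five evaluation runs as
#'   \code{system.file("extdata", "run_metrics.tsv", package = "strmps")}.
#' @return data.frame of run metrics.
#' @export
readRunMetrics <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (any(m$reads_pf > m$total_reads))
    stop("reads passing filter cannot exceed total reads")
  pc <- intersect(c("pct_pf", "pct_q30"), names(m))
  for (col in pc)
    if (any(m[[col]] < 0 | m[[col]] > 100))
      stop("percentage column out of [0, 100]: ", col)
  m
}
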