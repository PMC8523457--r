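#' @title File interchange and the end-to-end pipeline
#' @description TSV is the canonical interchange format (CSV accepted on
#'   read); UTF-8, Unix newlines, "." decimal separator regardless of
#'   locale. Designation strings are the on-disk allele representation —
#'   never floats: "9.3" is nine repeats plus three bases.
#' @name interface
NULL

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Read a sequence read-count table
#'
#' Expected columns: \code{sample_id}, \code{locus}, \code{sequence_id},
#' \code{reads}, plus the structure columns \code{units}, \code{partial},
#' \code{variant_ids} that make designation work possible downstream.
#'
#' @param path TSV/CSV path.
#' @param catalog optional \linkS4class{StrCatalog}; when given, loci are
#'   validated against it.
#' @return A \linkS4class{ReadProfileSet}.
#' @export
readReadcountTable <- function(path, catalog = NULL) {
  d <- .readTable(path)
  need <- c("sample_id", "locus", "sequence_id", "reads")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(d$reads < 0)
  if (length(bad))
    stop("negative read count at row ", bad[1L])
  key <- paste(d$sample_id, d$locus, d$sequence_id)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (sample, locus, sequence) at row ", dup[1L])
  if (!is.null(catalog)) {
    unknown <- which(!d$locus %in% catalog@loci$name)
    if (length(unknown))
      stop("unknown locus '", d$locus[unknown[1L]], "' at row ", unknown[1L])
  }
  if (!all(c("units", "partial") %in% names(d))) {
    warning("structure columns (units, partial) absent; ",
            "designation-dependent analyses will not be possible")
    d$units <- NA_integer_
    d$partial <- NA_integer_
  }
  if (!"variant_ids" %in% names(d)) d$variant_ids <- ""
  d$variant_ids[is.na(d$variant_ids)] <- ""
  seqs <- d[!duplicated(d$sequence_id),
            c("sequence_id", "locus", "units", "partial", "variant_ids")]
  rownames(seqs) <- NULL
  new("ReadProfileSet",
      reads = d[, c("sample_id", "locus", "sequence_id", "reads")],
      sequences = seqs)
}

#' Write a read-count table
#'
#' The inverse of \code{\link{readReadcountTable}}: reads joined with the
#' sequence structure columns, deterministic row order.
#'
#' @param profiles a \linkS4class{ReadProfileSet}.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeReadcountTable <- function(profiles, path) {
  rd <- profiles@reads
  sq <- profiles@sequences
  i <- match(rd$sequence_id, sq$sequence_id)
  rd$units <- sq$units[i]
  rd$partial <- sq$partial[i]
  rd$variant_ids <- sq$variant_ids[i]
  rd <- rd[order(rd$sample_id, rd$locus, rd$sequence_id), , drop = FALSE]
  write.table(rd, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a CE genotype table
#'
#' Columns \code{sample_id}, \code{locus}, \code{allele1}, \code{allele2};
#' micro-variants written "n.b". Malformed designation strings are reported
#' with their cell.
#'
#' @param path TSV/CSV path.
#' @return data.frame of CE genotypes.
#' @export
readCeTable <- function(path) {
  d <- .readTable(path)
  need <- c("sample_id", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("allele1", "allele2")) {
    d[[col]] <- as.character(d[[col]])
    for (i in seq_len(nrow(d))) {
      v <- d[[col]][i]
      if (is.na(v) || v == "") next
      ok <- tryCatch({ parseDesignation(v); TRUE },
                     error = function(e) FALSE)
      if (!ok)
        stop("malformed designation '", v, "' in column ", col,
             ", row ", i)
    }
  }
  d
}

#' Write a CE genotype table
#'
#' @param ce CE genotype data.frame.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeCeTable <- function(ce, path) {
  ce <- ce[order(ce$sample_id, ce$locus), , drop = FALSE]
  write.table(ce, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write a frequency table in wide (database-style) and long form
#'
#' @param freqs named list per locus of named frequency vectors.
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
writeFrequencyTables <- function(freqs, dir) {
  long <- do.call(rbind, lapply(names(freqs), function(locus)
    data.frame(locus = locus, allele = names(freqs[[locus]]),
               frequency = as.numeric(freqs[[locus]]),
               stringsAsFactors = FALSE)))
  long <- long[order(long$locus, long$allele), , drop = FALSE]
  longPath <- file.path(dir, "allele_frequencies_long.tsv")
  write.table(long, longPath, sep = "\t", quote = FALSE, row.names = FALSE)
  alleles <- sort(unique(long$allele))
  wide <- data.frame(allele = alleles, stringsAsFactors = FALSE)
  for (locus in sort(names(freqs))) {
    v <- freqs[[locus]][alleles]
    wide[[locus]] <- ifelse(is.na(v), "", format(v, digits = 6))
  }
  widePath <- file.path(dir, "allele_frequencies_wide.tsv")
  write.table(wide, widePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(longPath, widePath))
}

#' Run the full analysis pipeline
#'
#' Composes the stages in analysis order — analytical threshold, genotype
#' calling, pseudo-CE designation, QC (marker performance, heterozygote
#' balance, stutter), CE concordance, population statistics — and returns
#' one report bundle plus a manifest of versions, seed and thresholds.
#'
#' @param profiles a \linkS4class{ReadProfileSet}.
#' @param ceTable CE genotype data.frame (may be NULL to skip concordance).
#' @param catalog a \linkS4class{StrCatalog}.
#' @param at analytical threshold (reads, default 50).
#' @param itHom,itHet interpretation thresholds (reads, defaults 500/100).
#' @param hbFlag heterozygote-balance flag threshold (default 0.30).
#' @param stutterFlag excessive-stutter threshold (default 0.20).
#' @param categoryLow,categoryHigh read-depth category bounds.
#' @param hweSeed seed for the Hardy-Weinberg permutation fallback.
#' @param hweNPerm permutations for the Hardy-Weinberg Monte-Carlo fallback.
#' @return List: \code{calls}, \code{pseudo_ce}, \code{qc} (rmp, hb,
#'   stutter records and summary), \code{concordance}, \code{popstats},
#'   \code{manifest}.
#' @export
runPipeline <- function(profiles, ceTable, catalog, at = 50, itHom = 500,
                        itHet = 100, hbFlag = 0.30, stutterFlag = 0.20,
                        categoryLow = 63500, categoryHigh = 199000,
                        hweSeed = 1L, hweNPerm = 5000L) {
  if (!nrow(profiles@reads))
    stop("empty cohort: no read observations")
  filtered <- applyAnalyticalThreshold(profiles, at)
  calls <- callGenotypes(filtered, catalog, itHom = itHom, itHet = itHet)
  pce <- pseudoCeProfile(calls, profiles, catalog)
  rmp <- relativeMarkerPerformance(profiles)
  hb <- profileHeterozygoteBalance(calls, hbFlag)
  stut <- stutterRatios(profiles, calls, categoryLow, categoryHigh)
  stutSummary <- summarizeStutter(stut, stutterFlag)
  conc <- if (!is.null(ceTable))
    concordanceSummary(ceTable, pce$profile) else NULL
  cl <- calls@calls
  complete <- cl[!is.na(cl$seq_a), , drop = FALSE]
  pop <- locusPopStats(complete, hweSeed = hweSeed, hweNPerm = hweNPerm)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strmps")),
    thresholds = list(at = at, it_hom = itHom, it_het = itHet,
                      hb_flag = hbFlag, stutter_flag = stutterFlag,
                      category_low = categoryLow,
                      category_high = categoryHigh),
    hwe_seed = hweSeed,
    n_samples = length(unique(profiles@reads$sample_id)),
    n_sequences_removed_at = attr(filtered, "n_removed"))
  list(calls = calls, pseudo_ce = pce,
       qc = list(rmp = rmp, hb = hb, stutter = stut,
                 stutter_summary = stutSummary),
       concordance = conc, popstats = pop, manifest = manifest)
}

#' Write the pipeline report bundle to a directory
#'
#' Deterministic, byte-stable outputs given fixed inputs: stable ordering
#' and fixed decimal formatting.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
writeReports <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) {
    num <- vapply(d, is.numeric, NA)
    d[num] <- lapply(d[num], function(x) ifelse(is.na(x), NA,
                                                format(x, digits = 6)))
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  }
  wt(bundle$calls@calls, "genotype_calls.tsv")
  wt(bundle$qc$rmp, "marker_performance.tsv")
  wt(bundle$qc$hb, "heterozygote_balance.tsv")
  if (!is.null(bundle$qc$stutter) && nrow(bundle$qc$stutter))
    wt(bundle$qc$stutter, "stutter_records.tsv")
  wt(bundle$qc$stutter_summary, "stutter_summary.tsv")
  wt(bundle$popstats, "locus_popstats.tsv")
  if (!is.null(bundle$concordance)) {
    wt(bundle$concordance$events, "concordance_events.tsv")
    smry <- bundle$concordance
    smry$events <- NULL
    jsonlite::write_json(smry, file.path(dir, "concordance_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
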