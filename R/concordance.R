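#' @title CE versus MPS concordance
#' @description Compares CE genotypes with pseudo-CE designations
#'   recalculated from sequencing calls; classifies and quantifies
#'   discordances.
#' @name concordance
NULL

.multisetMatched <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
}

#' Compare one locus between CE and MPS
#'
#' Designation multisets are compared after normalisation; equality is exact
#' string equality (no size tolerance). A drop-out is an MPS profile missing
#' exactly one of the CE alleles (direction decided on designation value:
#' full units, then partial bases); a drop-in is an MPS allele absent from
#' CE; anything else non-equal is discordant.
#'
#' @param ce character vector of CE designation strings (multiset; a
#'   homozygote may be given once or twice).
#' @param mps character vector of MPS pseudo-CE designation strings
#'   (homozygous calls expanded to two copies by
#'   \code{\link{pseudoCeProfile}}).
#' @return List: \code{status} in \{concordant, dropout_shorter,
#'   dropout_longer, dropin, discordant, missing\} and
#'   \code{matched_allele_count}.
#' @export
compareLocus <- function(ce, mps) {
  ce <- ce[!is.na(ce)]
  mps <- mps[!is.na(mps)]
  if (!length(ce))
    return(list(status = if (length(mps)) "dropin" else "missing",
                matched_allele_count = 0L))
  matched <- .multisetMatched(ce, mps)
  if (length(ce) == length(mps) && matched == length(ce))
    return(list(status = "concordant", matched_allele_count = matched))
  ceSet <- unique(ce)
  mpsSet <- unique(mps)
  missing <- setdiff(ceSet, mpsSet)
  extra <- setdiff(mpsSet, ceSet)
  if (!length(mps) || (length(missing) >= 1L && !length(extra) &&
                       length(missing) == length(ceSet)))
    return(list(status = "discordant", matched_allele_count = matched))
  if (length(missing) == 1L && !length(extra)) {
    remaining <- setdiff(ceSet, missing)
    longer <- all(vapply(remaining, function(r)
      compareDesignation(missing, r) > 0L, NA))
    return(list(status = if (longer) "dropout_longer" else "dropout_shorter",
                matched_allele_count = matched))
  }
  if (length(extra) >= 1L && !length(missing))
    return(list(status = "dropin", matched_allele_count = matched))
  list(status = "discordant", matched_allele_count = matched)
}

#' Pseudo-CE designation multisets from genotype calls
#'
#' Applies the CE-equivalent designation arithmetic to each called allele and
#' also carries the naive repeat-count designation, so designation-method
#' mismatches (would-be false exclusions against a length-based database) are
#' reported. Homozygous calls are expanded to two copies of the single
#' allele.
#'
#' @param calls a \linkS4class{GenotypeCallSet}.
#' @param profiles the \linkS4class{ReadProfileSet} carrying the sequence
#'   annotation (units, partial, carried variants).
#' @param catalog a \linkS4class{StrCatalog}.
#' @return List with \code{profile} (data.frame \code{sample_id},
#'   \code{locus}, \code{alleles}: list column of pseudo-CE designation
#'   multisets) and \code{mismatches} (per-allele rows where pseudo-CE and
#'   naive repeat-count designations differ).
#' @export
pseudoCeProfile <- function(calls, profiles, catalog) {
  cl <- calls@calls
  sq <- profiles@sequences
  long <- rbind(
    data.frame(row = seq_len(nrow(cl)), seq = cl$seq_a,
               stringsAsFactors = FALSE),
    data.frame(row = seq_len(nrow(cl)), seq = cl$seq_b,
               stringsAsFactors = FALSE))
  long <- long[!is.na(long$seq), , drop = FALSE]
  i <- match(long$seq, sq$sequence_id)
  long$locus <- cl$locus[long$row]
  long$naive <- formatDesignation(sq$units[i], sq$partial[i])
  long$pseudo_ce <- ceDesignationString(catalog, long$locus, sq$units[i],
                                        sq$partial[i], sq$variant_ids[i])
  mism <- long[long$naive != long$pseudo_ce, , drop = FALSE]
  mismatches <- data.frame(sample_id = cl$sample_id[mism$row],
                           locus = mism$locus, sequence_id = mism$seq,
                           naive = mism$naive, pseudo_ce = mism$pseudo_ce,
                           stringsAsFactors = FALSE)
  alleles <- vector("list", nrow(cl))
  for (j in seq_len(nrow(long))) {
    r <- long$row[j]
    alleles[[r]] <- c(alleles[[r]], long$pseudo_ce[j])
  }
  hom <- which(cl$homozygous & !is.na(cl$seq_a))
  for (r in hom) alleles[[r]] <- rep(alleles[[r]][1L], 2L)
  prof <- data.frame(sample_id = cl$sample_id, locus = cl$locus,
                     stringsAsFactors = FALSE)
  prof$alleles <- alleles
  list(profile = prof, mismatches = mismatches)
}

#' Concordance summary over a cohort
#'
#' Allele concordance is the summed matched alleles over twice the number of
#' compared loci; locus concordance the fraction of fully concordant loci.
#' Both are reported in percent to two decimals.
#'
#' @param ceTable CE genotype data.frame (\code{sample_id}, \code{locus},
#'   \code{allele1}, \code{allele2}).
#' @param mpsProfile pseudo-CE profile data.frame from
#'   \code{\link{pseudoCeProfile}}.
#' @return List: \code{allele_concordance_pct}, \code{locus_concordance_pct},
#'   \code{total_alleles}, \code{total_loci}, \code{matched_alleles},
#'   \code{concordant_loci}, \code{events} (non-concordant comparisons).
#' @export
concordanceSummary <- function(ceTable, mpsProfile) {
  if (!nrow(ceTable)) stop("empty CE table")
  key <- paste(mpsProfile$sample_id, mpsProfile$locus, sep = "\r")
  idx <- match(paste(ceTable$sample_id, ceTable$locus, sep = "\r"), key)
  res <- lapply(seq_len(nrow(ceTable)), function(j) {
    ce <- c(ceTable$allele1[j], ceTable$allele2[j])
    mps <- if (is.na(idx[j])) character() else mpsProfile$alleles[[idx[j]]]
    cmp <- compareLocus(ce, mps)
    list(ce = paste(sort(ce), collapse = ","),
         mps = paste(sort(unlist(mps)), collapse = ","),
         status = cmp$status, matched = cmp$matched_allele_count)
  })
  comps <- data.frame(
    sample_id = ceTable$sample_id, locus = ceTable$locus,
    ce = vapply(res, `[[`, "", "ce"),
    mps = vapply(res, `[[`, "", "mps"),
    status = vapply(res, `[[`, "", "status"),
    matched = vapply(res, `[[`, 0L, "matched"),
    stringsAsFactors = FALSE)
  totalLoci <- nrow(comps)
  totalAlleles <- 2L * totalLoci
  matched <- sum(comps$matched)
  concordant <- sum(comps$status == "concordant")
  list(allele_concordance_pct = roundHalfUp(100 * matched / totalAlleles, 2),
       locus_concordance_pct = roundHalfUp(100 * concordant / totalLoci, 2),
       total_alleles = totalAlleles, total_loci = totalLoci,
       matched_alleles = matched, concordant_loci = concordant,
       events = comps[comps$status != "concordant", , drop = FALSE])
}
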