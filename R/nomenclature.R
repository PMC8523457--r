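#' @title Repeat-count and CE-equivalent allele designation
#' @description Converting sequenced alleles to repeat-unit designations and
#'   to CE-equivalent (pseudo-CE) designations that stay backward compatible
#'   with length-based databases, including micro-variant arithmetic for
#'   catalogued flanking indels.
#' @name nomenclature
NULL

#' Repeat-count designation of a sequenced allele
#'
#' Sums the unit counts of the counted blocks of the repeat region; leftover
#' counted bases become the partial (micro-variant) part. Uncounted blocks do
#' not contribute to the designation.
#'
#' @param allele a \linkS4class{SequenceAllele}.
#' @param catalog a \linkS4class{StrCatalog} supplying the locus period.
#' @return A \linkS4class{Designation}.
#' @examples
#' cat22 <- defaultCatalog()
#' a <- sequenceAllele("TPOX",
#'   data.frame(motif = "AATG", count = 8, counted = TRUE))
#' repeatDesignation(a, cat22)  # 8
#' @export
repeatDesignation <- function(allele, catalog) {
  period <- locusPeriod(catalog, allele@locus)
  if (is.na(period))
    stop("locus ", allele@locus, " is not an STR locus")
  if (allele@partialBases >= period)
    stop("partial bases (", allele@partialBases,
         ") must be smaller than the repeat period (", period, ")")
  b <- allele@blocks
  fu <- if (nrow(b)) sum(b$count[b$counted]) else 0L
  designation(fu, allele@partialBases)
}

#' CE-equivalent designation under catalogued flanking variants
#'
#' Converts a repeat-count designation to the designation a length-based
#' (CE) workflow would report for the same molecule. If any carried variant
#' has a catalogue \code{ce_designation_override}, that printed mapping wins.
#' Otherwise the counted length \code{L = units * period + partial} is
#' adjusted by the summed net length changes of the carried indels and
#' re-expressed in repeat units: \code{L div period} full units plus
#' \code{L mod period} bases. SNPs (net change 0) are the identity.
#'
#' @param repeatDes a \linkS4class{Designation} from repeat-unit counting.
#' @param locus locus name.
#' @param catalog a \linkS4class{StrCatalog}.
#' @param variantIds character vector of carried catalogue variant ids.
#' @return A \linkS4class{Designation}.
#' @examples
#' cat22 <- defaultCatalog()
#' # one-base flanking deletion: a 10-repeat D2S441 allele sizes as 9.3
#' ceEquivalentDesignation(designation(10), "D2S441", cat22, "rs888232687")
#' @export
ceEquivalentDesignation <- function(repeatDes, locus, catalog,
                                    variantIds = character()) {
  period <- locusPeriod(catalog, locus)
  if (is.na(period))
    stop("locus ", locus, " is not an STR locus")
  if (!length(variantIds))
    return(repeatDes)
  va <- do.call(rbind, lapply(variantIds, lookupVariant, catalog = catalog))
  if (any(va$locus != locus))
    stop("variant(s) ", paste(va$variant_id[va$locus != locus], collapse = ", "),
         " do not belong to locus ", locus)
  ov <- va$ce_designation_override[!is.na(va$ce_designation_override)]
  if (length(ov)) {
    p <- parseDesignation(ov[[1L]])
    return(designation(p$units, p$partial))
  }
  L <- repeatDes@fullUnits * period + repeatDes@partial +
    sum(va$net_length_change)
  if (L < 0L)
    stop("net deletion (", sum(va$net_length_change),
         ") exceeds allele length at ", locus)
  designation(L %/% period, L %% period)
}

#' Vectorised CE-equivalent designation strings
#'
#' Bulk form of \code{\link{ceEquivalentDesignation}} for annotation tables:
#' takes repeat units, partial bases and comma-separated carried variant ids
#' and returns designation strings.
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param locus character vector of locus names.
#' @param units integer vector of full repeat units.
#' @param partial integer vector of leftover bases.
#' @param variantIds character vector of comma-separated variant ids
#'   ("" for none).
#' @return Character vector of CE-equivalent designation strings.
#' @export
ceDesignationString <- function(catalog, locus, units, partial = 0L,
                                variantIds = "") {
  n <- length(locus)
  units <- rep_len(as.integer(units), n)
  partial <- rep_len(as.integer(partial), n)
  variantIds <- rep_len(as.character(variantIds), n)
  variantIds[is.na(variantIds)] <- ""
  out <- character(n)
  plain <- !nzchar(variantIds)
  out[plain] <- formatDesignation(units[plain], partial[plain])
  for (i in which(!plain)) {
    ids <- strsplit(variantIds[i], ",", fixed = TRUE)[[1L]]
    ids <- trimws(ids[nzchar(trimws(ids))])
    d <- ceEquivalentDesignation(designation(units[i], partial[i]),
                                 locus[i], catalog, ids)
    out[i] <- formatDesignation(d@fullUnits, d@partial)
  }
  out
}

#' Classify genotypes as length/sequence homo- or heterozygous
#'
#' A genotype whose two alleles share the length designation but differ in
#' sequence is an isometric heterozygote: invisible to CE, resolved by
#' sequencing. Input is a genotype table with sequence detail (columns
#' \code{sample_id}, \code{locus}, \code{seq_a}, \code{seq_b}, \code{des_a},
#' \code{des_b}; homozygotes may carry \code{seq_b = NA}).
#'
#' @param genotypes genotype data.frame with sequence detail.
#' @return List with \code{genotypes} (input plus a \code{class} column with
#'   levels length_hom_seq_hom / length_hom_seq_het / length_het),
#'   \code{by_locus} (per-locus counts and isometric reclassifications), and
#'   \code{reclassified_pct} (percentage of length-homozygous genotypes
#'   unveiled as isometric heterozygotes, one decimal).
#' @export
detectIsoalleles <- function(genotypes) {
  g <- genotypes
  seqB <- ifelse(is.na(g$seq_b), g$seq_a, g$seq_b)
  desB <- ifelse(is.na(g$des_b), g$des_a, g$des_b)
  cls <- ifelse(g$des_a != desB, "length_het",
         ifelse(g$seq_a == seqB, "length_hom_seq_hom", "length_hom_seq_het"))
  g$class <- cls
  tab <- table(locus = g$locus, class = factor(
    cls, levels = c("length_hom_seq_hom", "length_hom_seq_het", "length_het")))
  byLocus <- data.frame(
    locus = rownames(tab),
    length_hom_seq_hom = as.integer(tab[, "length_hom_seq_hom"]),
    isometric_het = as.integer(tab[, "length_hom_seq_het"]),
    length_het = as.integer(tab[, "length_het"]),
    row.names = NULL)
  nHom <- sum(byLocus$length_hom_seq_hom) + sum(byLocus$isometric_het)
  pct <- if (nHom > 0)
    roundHalfUp(100 * sum(byLocus$isometric_het) / nHom, 1) else NA_real_
  list(genotypes = g, by_locus = byLocus,
       n_length_hom = nHom,
       n_reclassified = sum(byLocus$isometric_het),
       reclassified_pct = pct)
}

#' Length- versus sequence-level allele diversity per locus
#'
#' For each locus: distinct length-based alleles, distinct sequence-based
#' alleles, their difference, the fold increase (sequence/length, half-up to
#' one decimal), and observed heterozygosity at both resolution levels.
#'
#' @param genotypes genotype data.frame with sequence detail (as in
#'   \code{\link{detectIsoalleles}}).
#' @return data.frame, one row per locus.
#' @export
summarizeAlleleDiversity <- function(genotypes) {
  g <- genotypes
  g$seq_b2 <- ifelse(is.na(g$seq_b), g$seq_a, g$seq_b)
  g$des_b2 <- ifelse(is.na(g$des_b), g$des_a, g$des_b)
  res <- lapply(split(g, g$locus), function(d) {
    lenAll <- unique(c(d$des_a, d$des_b2))
    seqAll <- unique(c(d$seq_a, d$seq_b2))
    nLen <- length(lenAll)
    nSeq <- length(seqAll)
    data.frame(
      locus = d$locus[1L],
      n_length_alleles = nLen,
      n_sequence_alleles = nSeq,
      n_additional = nSeq - nLen,
      fold_increase = roundHalfUp(nSeq / nLen, 1),
      h_obs_length = round(mean(d$des_a != d$des_b2), 2),
      h_obs_sequence = round(mean(d$seq_a != d$seq_b2), 2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$n_additional, out$locus), , drop = FALSE]
}
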