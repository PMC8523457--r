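#' @import methods
#' @importFrom stats aggregate median rbeta rlnorm rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

setClassUnion("dataFrameOrNULL", c("data.frame", "NULL"))

#' Catalogue of STR loci and sequence variants
#'
#' Holds the locus definitions of a sequencing panel (repeat period, canonical
#' motif, the ordered counted/uncounted block template of the repeat region)
#' and the catalogue of flanking/repeat variants that drive CE-equivalent
#' designation arithmetic. The shipped default describes the 22 autosomal STRs
#' plus amelogenin of the PowerSeq 46GY panel.
#'
#' @slot loci data.frame with columns \code{name}, \code{period} (repeat unit
#'   length in bases; NA for non-STR markers such as amelogenin), \code{motif},
#'   \code{is_str}, and a list column \code{blocks} of data.frames
#'   (\code{motif}, \code{counted}) describing the repeat-region template.
#' @slot variants data.frame with columns \code{variant_id}, \code{locus},
#'   \code{kind} (SNP/insertion/deletion), \code{region}, \code{net_length_change},
#'   \code{ce_designation_override}, \code{note}.
#' @slot panelMarkerCount integer, markers in the panel including amelogenin.
#'
#' @exportClass StrCatalog
setClass("StrCatalog",
  representation(loci = "data.frame", variants = "data.frame",
                 panelMarkerCount = "integer"),
  validity = function(object) {
    lo <- object@loci
    need <- c("name", "period", "motif", "is_str", "blocks")
    if (!all(need %in% names(lo)))
      return(paste("loci must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(lo$name))
      return("duplicate locus name in catalogue")
    str <- lo[lo$is_str, , drop = FALSE]
    if (nrow(str)) {
      if (!all(str$period %in% c(3L, 4L, 5L)))
        return("STR locus period must be 3, 4 or 5")
      if (!all(nchar(str$motif) == str$period))
        return("motif length must equal period")
      nct <- vapply(str$blocks, function(b) sum(b$counted), integer(1))
      if (any(nct < 1L))
        return("every STR locus needs at least one counted block")
    }
    va <- object@variants
    needv <- c("variant_id", "locus", "kind", "region", "net_length_change",
               "ce_designation_override", "note")
    if (!all(needv %in% names(va)))
      return(paste("variants must have columns:", paste(needv, collapse = ", ")))
    if (anyDuplicated(va$variant_id))
      return("duplicate variant_id in catalogue")
    bad <- setdiff(va$locus, lo$name)
    if (length(bad))
      return(paste("variant references undefined locus:",
                   paste(bad, collapse = ", ")))
    if (!all(va$kind %in% c("SNP", "insertion", "deletion")))
      return("variant kind must be SNP, insertion or deletion")
    if (any(va$kind == "SNP" & va$net_length_change != 0L))
      return("SNP variants must have net_length_change 0")
    if (any(va$kind == "deletion" & va$net_length_change >= 0L))
      return("deletion variants must have net_length_change < 0")
    if (any(va$kind == "insertion" & va$net_length_change <= 0L))
      return("insertion variants must have net_length_change > 0")
    if (object@panelMarkerCount < 1L)
      return("panelMarkerCount must be >= 1")
    TRUE
  })

setMethod("show", "StrCatalog", function(object) {
  cat("StrCatalog:", nrow(object@loci), "loci (",
      sum(object@loci$is_str), "STR ),",
      nrow(object@variants), "catalogued variants;",
      "panel of", object@panelMarkerCount, "markers\n")
})

#' A sequenced STR allele
#'
#' The repeat-region structure of one sequenced allele: ordered
#' \code{(motif, count)} blocks flagged counted/uncounted toward the
#' designation, leftover counted bases, and references into the variant
#' catalogue for flanking variants carried by the allele.
#'
#' @slot locus character, locus name.
#' @slot blocks data.frame with columns \code{motif}, \code{count},
#'   \code{counted}.
#' @slot partialBases integer, leftover counted bases (0..period-1).
#' @slot variantIds character vector of catalogue variant ids.
#' @slot sequenceId character, stable identifier of the sequence.
#'
#' @exportClass SequenceAllele
setClass("SequenceAllele",
  representation(locus = "character", blocks = "data.frame",
                 partialBases = "integer", variantIds = "character",
                 sequenceId = "character"),
  validity = function(object) {
    if (!all(c("motif", "count", "counted") %in% names(object@blocks)))
      return("blocks needs columns motif, count, counted")
    if (nrow(object@blocks) && any(object@blocks$count < 0L))
      return("block counts must be >= 0")
    if (object@partialBases < 0L)
      return("partialBases must be >= 0")
    TRUE
  })

#' Construct a SequenceAllele
#'
#' @param locus locus name.
#' @param blocks data.frame(motif, count, counted) of ordered repeat blocks.
#' @param partialBases leftover counted bases.
#' @param variantIds catalogue ids of flanking variants carried.
#' @param sequenceId stable sequence identifier.
#' @return A \linkS4class{SequenceAllele}.
#' @export
sequenceAllele <- function(locus, blocks, partialBases = 0L,
                           variantIds = character(), sequenceId = NA_character_) {
  blocks$count <- as.integer(blocks$count)
  new("SequenceAllele", locus = locus, blocks = blocks,
      partialBases = as.integer(partialBases),
      variantIds = as.character(variantIds),
      sequenceId = as.character(sequenceId))
}

setMethod("show", "SequenceAllele", function(object) {
  br <- paste0("[", object@blocks$motif, "]", object@blocks$count,
               ifelse(object@blocks$counted, "", "*"), collapse = " ")
  cat("SequenceAllele", object@sequenceId, "at", object@locus, ":", br)
  if (object@partialBases > 0L) cat(" +", object@partialBases, "bases")
  if (length(object@variantIds))
    cat(" |", paste(object@variantIds, collapse = ","))
  cat("\n")
})

#' Per-sample sequence read counts
#'
#' Container for per-sample, per-locus sequence-level read counts, together
#' with the structural annotation (repeat units, partial bases, carried
#' variants) of every observed sequence.
#'
#' @slot reads data.frame with columns \code{sample_id}, \code{locus},
#'   \code{sequence_id}, \code{reads} (non-negative integers).
#' @slot sequences data.frame with columns \code{sequence_id}, \code{locus},
#'   \code{units}, \code{partial}, \code{variant_ids} (comma-separated ids,
#'   "" for none).
#'
#' @exportClass ReadProfileSet
setClass("ReadProfileSet",
  representation(reads = "data.frame", sequences = "data.frame"),
  validity = function(object) {
    rd <- object@reads
    need <- c("sample_id", "locus", "sequence_id", "reads")
    if (!all(need %in% names(rd)))
      return(paste("reads must have columns:", paste(need, collapse = ", ")))
    if (nrow(rd)) {
      if (any(rd$reads < 0))
        return("read counts must be >= 0")
      if (any(rd$reads != as.integer(rd$reads)))
        return("read counts must be integers")
      key <- paste(rd$sample_id, rd$locus, rd$sequence_id)
      if (anyDuplicated(key))
        return("duplicate (sample, locus, sequence) entry")
    }
    sq <- object@sequences
    needs <- c("sequence_id", "locus", "units", "partial", "variant_ids")
    if (!all(needs %in% names(sq)))
      return(paste("sequences must have columns:",
                   paste(needs, collapse = ", ")))
    if (anyDuplicated(sq$sequence_id))
      return("duplicate sequence_id in annotation")
    TRUE
  })

setMethod("show", "ReadProfileSet", function(object) {
  cat("ReadProfileSet:", length(unique(object@reads$sample_id)), "samples,",
      length(unique(object@reads$locus)), "markers,",
      nrow(object@reads), "sequence observations\n")
})

#' Thresholded genotype calls
#'
#' One row per sample and locus; homozygotes carry a single allele plus the
#' \code{homozygous} marker (never a duplicated allele record), so allele
#' counting stays unambiguous downstream.
#'
#' @slot calls data.frame with columns \code{sample_id}, \code{locus},
#'   \code{seq_a}, \code{seq_b}, \code{reads_a}, \code{reads_b}, \code{des_a},
#'   \code{des_b}, \code{homozygous}, \code{flags} (comma-separated subset of
#'   below_AT_removed, possible_dropout, no_call, imbalanced, triallelic).
#'
#' @exportClass GenotypeCallSet
setClass("GenotypeCallSet",
  representation(calls = "data.frame"),
  validity = function(object) {
    need <- c("sample_id", "locus", "seq_a", "seq_b", "reads_a", "reads_b",
              "des_a", "des_b", "homozygous", "flags")
    if (!all(need %in% names(object@calls)))
      return(paste("calls must have columns:", paste(need, collapse = ", ")))
    cl <- object@calls
    if (nrow(cl) && any(cl$homozygous & !is.na(cl$seq_b)))
      return("homozygous calls must carry a single allele record")
    TRUE
  })

setMethod("show", "GenotypeCallSet", function(object) {
  cl <- object@calls
  cat("GenotypeCallSet:", nrow(cl), "locus calls;",
      sum(!is.na(cl$seq_a)), "called,",
      sum(grepl("no_call", cl$flags)), "no-calls\n")
})

#' Accessor generics
#'
#' @param x object.
#' @param ... further arguments.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("loci", function(x, ...) standardGeneric("loci"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x, ...) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("panelMarkerCount", function(x, ...)
  standardGeneric("panelMarkerCount"))
#' @rdname accessors
#' @export
setGeneric("profileReads", function(x, ...) standardGeneric("profileReads"))
#' @rdname accessors
#' @export
setGeneric("sequenceInfo", function(x, ...) standardGeneric("sequenceInfo"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x, ...) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setMethod("loci", "StrCatalog", function(x, ...) x@loci)
#' @rdname accessors
#' @export
setMethod("variants", "StrCatalog", function(x, ...) x@variants)
#' @rdname accessors
#' @export
setMethod("panelMarkerCount", "StrCatalog", function(x, ...)
  x@panelMarkerCount)
#' @rdname accessors
#' @export
setMethod("profileReads", "ReadProfileSet", function(x, ...) x@reads)
#' @rdname accessors
#' @export
setMethod("sequenceInfo", "ReadProfileSet", function(x, ...) x@sequences)
#' @rdname accessors
#' @export
setMethod("sampleIds", "ReadProfileSet", function(x, ...)
  unique(x@reads$sample_id))
#' @rdname accessors
#' @export
setMethod("totalReads", "ReadProfileSet", function(x, ...) {
  tapply(x@reads$reads, x@reads$sample_id, sum)[unique(x@reads$sample_id)]
})
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeCallSet", function(x, ...) x@calls)

#' Names of the STR loci in a catalogue
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @return Character vector of STR locus names (amelogenin excluded).
#' @export
strLocusNames <- function(catalog) {
  catalog@loci$name[catalog@loci$is_str]
}

#' Repeat period of a locus
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param locus locus name(s).
#' @return Integer vector of repeat-unit lengths in bases.
#' @export
locusPeriod <- function(catalog, locus) {
  i <- match(locus, catalog@loci$name)
  if (anyNA(i))
    stop("unknown locus: ", paste(locus[is.na(i)], collapse = ", "))
  catalog@loci$period[i]
}
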