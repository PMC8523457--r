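#' @title Locus and variant catalogue
#' @description Loading, validation and export of the panel catalogue that
#'   drives designation arithmetic and simulation.
#' @name catalog
NULL

.lociToDf <- function(loci) {
  blocks <- lapply(loci, function(l) {
    b <- l$blocks
    data.frame(motif = vapply(b, `[[`, "", "motif"),
               counted = vapply(b, `[[`, NA, "counted"))
  })
  data.frame(
    name = vapply(loci, `[[`, "", "name"),
    period = vapply(loci, function(l)
      if (is.null(l$period)) NA_integer_ else as.integer(l$period), integer(1)),
    motif = vapply(loci, function(l)
      if (is.null(l$motif)) "" else l$motif, ""),
    is_str = vapply(loci, function(l) isTRUE(l$is_str), NA),
    blocks = I(blocks),
    stringsAsFactors = FALSE)
}

.variantsToDf <- function(vars) {
  if (!length(vars))
    return(data.frame(variant_id = character(), locus = character(),
                      kind = character(), region = character(),
                      net_length_change = integer(),
                      ce_designation_override = character(),
                      note = character(), stringsAsFactors = FALSE))
  g <- function(f, default) vapply(vars, function(v)
    if (is.null(v[[f]])) default else v[[f]],
    default)
  data.frame(
    variant_id = g("variant_id", ""),
    locus = g("locus", ""),
    kind = g("kind", ""),
    region = g("region", ""),
    net_length_change = as.integer(g("net_length_change", 0)),
    ce_designation_override = {
      x <- vapply(vars, function(v)
        if (is.null(v$ce_designation_override)) NA_character_
        else as.character(v$ce_designation_override), "")
      x
    },
    note = g("note", ""),
    stringsAsFactors = FALSE)
}

#' Load a catalogue from JSON
#'
#' The JSON schema (version 1) has top-level fields \code{schema_version},
#' \code{panel_marker_count}, \code{loci} and \code{variants}. Block
#' coordinates are 0-based half-open relative to the repeat-region start on
#' the catalogue's stated reference strand.
#'
#' @param path path to a catalogue JSON file.
#' @return A validated \linkS4class{StrCatalog}.
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path))
    stop("catalogue file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$schema_version) || js$schema_version != 1L)
    stop("unsupported catalogue schema version")
  new("StrCatalog",
      loci = .lociToDf(js$loci),
      variants = .variantsToDf(js$variants),
      panelMarkerCount = as.integer(js$panel_marker_count))
}

#' Write a catalogue to JSON
#'
#' \code{loadCatalog(writeCatalog(x, f))} reproduces an equivalent catalogue
#' field by field.
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  lo <- catalog@loci
  loci <- lapply(seq_len(nrow(lo)), function(i) {
    b <- lo$blocks[[i]]
    l <- list(name = lo$name[i], is_str = lo$is_str[i],
              blocks = lapply(seq_len(nrow(b)), function(j)
                list(motif = b$motif[j], counted = b$counted[j])))
    if (!is.na(lo$period[i])) l$period <- lo$period[i]
    if (nzchar(lo$motif[i])) l$motif <- lo$motif[i]
    l
  })
  va <- catalog@variants
  vars <- lapply(seq_len(nrow(va)), function(i) {
    v <- list(variant_id = va$variant_id[i], locus = va$locus[i],
              kind = va$kind[i], region = va$region[i],
              net_length_change = va$net_length_change[i],
              note = va$note[i])
    if (!is.na(va$ce_designation_override[i]))
      v$ce_designation_override <- va$ce_designation_override[i]
    v
  })
  jsonlite::write_json(
    list(schema_version = 1L,
         panel_marker_count = catalog@panelMarkerCount,
         loci = loci, variants = vars),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export the variant catalogue as TSV for human review
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
exportCatalogTsv <- function(catalog, path) {
  write.table(catalog@variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Look up a variant by identifier
#'
#' @param catalog a \linkS4class{StrCatalog}.
#' @param variantId dbSNP-style identifier.
#' @return One-row data.frame with the catalogue entry.
#' @export
lookupVariant <- function(catalog, variantId) {
  i <- match(variantId, catalog@variants$variant_id)
  if (is.na(i))
    stop("variant not found in catalogue: ", variantId)
  catalog@variants[i, , drop = FALSE]
}

#' The shipped default panel catalogue
#'
#' 22 autosomal STRs plus amelogenin (PowerSeq 46GY panel membership), with
#' the named flanking/repeat variants at D2S441, D19S433, Penta D, D5S818 and
#' TPOX that drive the worked designation examples.
#'
#' @return A \linkS4class{StrCatalog}.
#' @export
defaultCatalog <- function() {
  loadCatalog(system.file("extdata", "powerseq46gy_catalog.json",
                          package = "strmps", mustWork = TRUE))
}
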