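#' @title Allele designations
#'
#' @description STR alleles are designated by repeat count in the CE
#' convention: an integer allele is written \code{"n"} and a micro-variant
#' (intermediate) allele \code{"n.b"}, where \code{n} is the number of full
#' repeat units and \code{b} the number of leftover bases
#' (\code{0 <= b < period}). \code{"9.3"} means 9 full units plus 3 bases,
#' never 9.3 units.
#'
#' @name Designation
NULL

#' Designation of an STR allele
#'
#' @slot fullUnits integer, number of complete repeat units.
#' @slot partial integer, leftover counted bases (0 renders an integer allele).
#'
#' @exportClass Designation
setClass("Designation",
  representation(fullUnits = "integer", partial = "integer"),
  validity = function(object) {
    if (length(object@fullUnits) != 1L || length(object@partial) != 1L)
      return("fullUnits and partial must be length 1")
    if (is.na(object@fullUnits) || object@fullUnits < 0L)
      return("fullUnits must be a non-negative integer")
    if (is.na(object@partial) || object@partial < 0L)
      return("partial must be a non-negative integer")
    TRUE
  })

#' Create a Designation
#'
#' @param fullUnits number of complete repeat units.
#' @param partial leftover counted bases; 0 gives an integer allele.
#' @return A \linkS4class{Designation}.
#' @examples
#' designation(9, 3)   # rendered "9.3"
#' designation(12)     # rendered "12"
#' @export
designation <- function(fullUnits, partial = 0L) {
  new("Designation", fullUnits = as.integer(fullUnits),
      partial = as.integer(partial))
}

setMethod("show", "Designation", function(object) {
  cat("Designation:", formatDesignation(object@fullUnits, object@partial), "\n")
})

#' Render designations as strings
#'
#' Vectorised; the CE convention \code{"n"} / \code{"n.b"} is used, with
#' \code{b} in bases.
#'
#' @param units integer vector of full repeat units.
#' @param partial integer vector of leftover bases.
#' @return Character vector of designation strings.
#' @export
formatDesignation <- function(units, partial = 0L) {
  units <- as.integer(units)
  partial <- as.integer(rep_len(partial, length(units)))
  ifelse(partial == 0L, as.character(units), paste0(units, ".", partial))
}

#' Parse designation strings
#'
#' Accepts \code{"12"} and \code{"12.2"} forms. Anything else (floats with
#' trailing zeros, empty strings, letters) is rejected: designations are
#' labels, not numbers.
#'
#' @param x character vector of designation strings.
#' @return data.frame with integer columns \code{units} and \code{partial}.
#' @export
parseDesignation <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]+(\\.[1-9][0-9]*)?$", x)
  if (any(!ok))
    stop("malformed designation string(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  parts <- strsplit(x, ".", fixed = TRUE)
  units <- vapply(parts, function(p) as.integer(p[[1L]]), integer(1))
  partial <- vapply(parts, function(p)
    if (length(p) > 1L) as.integer(p[[2L]]) else 0L, integer(1))
  data.frame(units = units, partial = partial)
}

#' Order designations by length
#'
#' "Longer" and "shorter" are decided on the designation value — full units
#' first, then partial bases — not on amplicon size.
#'
#' @param a,b designation strings.
#' @return Integer vector: -1 if a < b, 0 if equal, 1 if a > b.
#' @export
compareDesignation <- function(a, b) {
  da <- parseDesignation(a)
  db <- parseDesignation(b)
  s <- sign(da$units - db$units)
  tie <- s == 0L
  s[tie] <- sign(da$partial - db$partial)[tie]
  as.integer(s)
}

# round half up at `digits` decimals (printed-table convention; R's round()
# is half-to-even which would print 3.25 -> 3.2)
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
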