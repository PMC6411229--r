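# Phosphosite identifiers.
#
# A phosphosite is a specific phosphorylatable residue on a protein,
# identified by (protein, residue, position). The canonical string form is
# "<protein>_<residue><position>", e.g. "NDRG1_S330". Protein labels may
# themselves contain underscores (isoform suffixes are kept verbatim); the
# site token is always the final underscore-delimited field.

.SITE_REGEX <- "^(.+)_([STY])([0-9]+)$"

#' Parse canonical phosphosite identifiers
#'
#' Splits identifiers of the form `"<protein>_<residue><position>"` (for
#' example `"NDRG1_S330"`) into their components. The residue must be one of
#' S, T or Y (serine, threonine, tyrosine) and the position a positive
#' 1-based integer. Parsing is the inverse of [format_site_id()].
#'
#' @param x character vector of site identifiers.
#' @return A data.frame with columns `protein` (character), `residue`
#'   (character, one of `"S"`, `"T"`, `"Y"`) and `position` (integer).
#' @examples
#' parse_site_id(c("NDRG1_S330", "AKT1S1_T246"))
#' @export
parse_site_id <- function(x) {
  stopifnot(is.character(x))
  ok <- grepl(.SITE_REGEX, x)
  if (!all(ok)) {
    stop("malformed site identifier(s): ",
         paste(utils::head(x[!ok], 5L), collapse = ", "))
  }
  protein <- sub(.SITE_REGEX, "\\1", x)
  residue <- sub(.SITE_REGEX, "\\2", x)
  position <- as.integer(sub(.SITE_REGEX, "\\3", x))
  if (any(position < 1L)) {
    stop("site position must be >= 1")
  }
  data.frame(protein = protein, residue = residue, position = position,
             stringsAsFactors = FALSE)
}

#' Format phosphosites as canonical identifiers
#'
#' @param protein character vector of protein accessions or gene symbols.
#' @param residue character vector of residue letters (S, T or Y).
#' @param position integer vector of 1-based sequence positions.
#' @return Character vector `"<protein>_<residue><position>"`.
#' @examples
#' format_site_id("NDRG1", "S", 330)
#' @export
format_site_id <- function(protein, residue, position) {
  if (!all(residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y")
  }
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) {
    stop("position must be a positive integer")
  }
  paste0(protein, "_", residue, position)
}

is_site_id <- function(x) grepl(.SITE_REGEX, x)
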