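## Pattern validation for the three identifier vocabularies.
## Gene symbols: uppercase alphanumeric plus hyphen, compared after
## uppercasing. ICD-10-CM codes: letter + 2 alphanumerics, optional
## sub-code after '.'. Pathway identifiers: class prefix ko / M / H.

.GENE_PATTERN <- "^[A-Z0-9][A-Z0-9-]*$"
.ICD_PATTERN <- "^[A-Z][0-9A-Z]{2}(\\.[0-9A-Z]{1,4})?$"
.PATHWAY_PATTERN <- "^(ko|M|H)[0-9]+$"
.RANGE_PATTERN <- "^[A-Z][0-9A-Z]{2}-[A-Z][0-9A-Z]{2}$"

#' Normalize and validate gene symbols
#'
#' Uppercases symbols and checks them against the symbol grammar
#' (uppercase alphanumerics plus hyphen, non-empty, no whitespace).
#'
#' @param x character vector of raw symbols.
#' @return uppercased character vector; invalid entries yield `NA`.
#' @keywords internal
normalize_gene_symbol <- function(x) {
  out <- toupper(trimws(x))
  out[!grepl(.GENE_PATTERN, out)] <- NA_character_
  out
}

#' @keywords internal
normalize_icd_code <- function(x) {
  out <- toupper(trimws(x))
  out[!grepl(.ICD_PATTERN, out)] <- NA_character_
  out
}

#' @keywords internal
validate_pathway_id <- function(x) {
  out <- trimws(x)
  out[!grepl(.PATHWAY_PATTERN, out)] <- NA_character_
  out
}

#' Pathway identifier class
#'
#' Extracts the identifier class (`"ko"` pathway map, `"M"` module,
#' `"H"` disease entry) from pathway ids.
#'
#' @param id character vector of pathway identifiers.
#' @return character vector in `c("ko", "M", "H")`.
#' @export
#' @examples
#' pathway_class(c("ko00010", "M00001", "H00027"))
pathway_class <- function(id) {
  cls <- sub("^(ko|M|H)[0-9]+$", "\\1", id)
  bad <- !cls %in% c("ko", "M", "H")
  if (any(bad)) {
    dz_error("diseasome_parse_error",
             sprintf("invalid pathway identifier(s): %s",
                     paste(id[bad], collapse = ", ")))
  }
  cls
}
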