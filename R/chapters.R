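#' The 21 ICD-10-CM chapters
#'
#' The standard chapter table of ICD-10-CM: 21 ranges of 3-character code
#' blocks with their names. Codes in the `U00-U85` block (codes for special
#' purposes) and the unused `T89-T99` block fall outside every chapter and
#' are reported as unassignable by [assign_chapter()].
#'
#' @return data.frame with columns `range`, `name`, plus derived `start`
#'   and `end` 3-character block bounds.
#' @export
#' @examples
#' icd10_chapters()[1:3, ]
icd10_chapters <- function() {
  tab <- matrix(c(
    "A00-B99", "Certain infectious and parasitic diseases",
    "C00-D49", "Neoplasms",
    "D50-D89", "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
    "E00-E89", "Endocrine, nutritional and metabolic diseases",
    "F01-F99", "Mental, behavioral and neurodevelopmental disorders",
    "G00-G99", "Diseases of the nervous system",
    "H00-H59", "Diseases of the eye and adnexa",
    "H60-H95", "Diseases of the ear and mastoid process",
    "I00-I99", "Diseases of the circulatory system",
    "J00-J99", "Diseases of the respiratory system",
    "K00-K95", "Diseases of the digestive system",
    "L00-L99", "Diseases of the skin and subcutaneous tissue",
    "M00-M99", "Diseases of the musculoskeletal system and connective tissue",
    "N00-N99", "Diseases of the genitourinary system",
    "O00-O9A", "Pregnancy, childbirth and the puerperium",
    "P00-P96", "Certain conditions originating in the perinatal period",
    "Q00-Q99", "Congenital malformations, deformations and chromosomal abnormalities",
    "R00-R99", "Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified",
    "S00-T88", "Injury, poisoning and certain other consequences of external causes",
    "V00-Y99", "External causes of morbidity",
    "Z00-Z99", "Factors influencing health status and contact with health services"
  ), ncol = 2, byrow = TRUE)
  chapters <- data.frame(range = tab[, 1], name = tab[, 2],
                         stringsAsFactors = FALSE)
  chapters$start <- substr(chapters$range, 1, 3)
  chapters$end <- substr(chapters$range, 5, 7)
  chapters
}

## ICD tabular order for a 3-character block: the leading letter orders
## first; positions 2-3 order character-wise with digits before letters,
## so "O99" < "O9A". Encoded as an integer rank.
icd_block_rank <- function(block) {
  stopifnot(all(nchar(block) == 3))
  chr_rank <- function(ch) {
    r <- match(ch, c(as.character(0:9), LETTERS)) - 1L
    if (anyNA(r)) {
      dz_error("diseasome_parse_error",
               "invalid character in ICD code block")
    }
    r
  }
  c1 <- match(substr(block, 1, 1), LETTERS) - 1L
  if (anyNA(c1)) {
    dz_error("diseasome_parse_error", "ICD code must start with a letter")
  }
  c1 * 1296L + chr_rank(substr(block, 2, 2)) * 36L +
    chr_rank(substr(block, 3, 3))
}

#' Validate an ICD chapter table
#'
#' Checks that ranges are well-formed, that each range's start does not
#' exceed its end, and that no two ranges overlap under ICD ordering.
#'
#' @param chapters data.frame with columns `range`, `name` (and optionally
#'   precomputed `start`/`end`).
#' @return the table with `start`/`end` columns, invisibly usable downstream.
#' @export
validate_chapters <- function(chapters) {
  if (!all(c("range", "name") %in% names(chapters))) {
    dz_error("diseasome_parse_error",
             "chapter table needs columns 'range' and 'name'")
  }
  bad <- !grepl(.RANGE_PATTERN, chapters$range)
  if (any(bad)) {
    dz_error("diseasome_parse_error",
             sprintf("malformed chapter range(s): %s",
                     paste(chapters$range[bad], collapse = ", ")))
  }
  chapters$start <- substr(chapters$range, 1, 3)
  chapters$end <- substr(chapters$range, 5, 7)
  s <- icd_block_rank(chapters$start)
  e <- icd_block_rank(chapters$end)
  if (any(s > e)) {
    dz_error("diseasome_parse_error", "chapter range start exceeds end")
  }
  o <- order(s)
  if (any(s[o][-1] <= e[o][-length(e)])) {
    dz_error("diseasome_parse_error", "chapter ranges overlap")
  }
  chapters
}

#' Assign ICD-10-CM codes to chapters
#'
#' Maps each code to the unique chapter whose block range contains the
#' code's first three characters under ICD tabular ordering (digits sort
#' before letters at positions 2-3, so `"O9A"` falls inside `O00-O9A`
#' even though `"O99" < "O9A"` fails plain lexicographic order).
#'
#' @param codes character vector of ICD-10-CM codes (sub-codes after `.`
#'   are ignored for chapter membership).
#' @param chapters chapter table as from [icd10_chapters()].
#' @return character vector of chapter range labels, one per code.
#' @export
#' @examples
#' assign_chapter(c("C34", "O9A", "S10.1"))
assign_chapter <- function(codes, chapters = icd10_chapters()) {
  chapters <- validate_chapters(chapters)
  codes_norm <- normalize_icd_code(codes)
  if (anyNA(codes_norm)) {
    dz_error("diseasome_parse_error",
             sprintf("malformed ICD-10-CM code(s): %s",
                     paste(codes[is.na(codes_norm)], collapse = ", ")))
  }
  block <- substr(codes_norm, 1, 3)
  r <- icd_block_rank(block)
  s <- icd_block_rank(chapters$start)
  e <- icd_block_rank(chapters$end)
  idx <- vapply(r, function(ri) {
    hit <- which(s <= ri & ri <= e)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(idx)) {
    dz_error("diseasome_unassignable_code",
             sprintf("code(s) outside every chapter range: %s",
                     paste(unique(codes_norm[is.na(idx)]), collapse = ", ")),
             codes = unique(codes_norm[is.na(idx)]))
  }
  chapters$range[idx]
}
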