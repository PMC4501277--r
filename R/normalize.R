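#' Normalize gene symbols against an authority table
#'
#' Rewrites every gene symbol in a disease-gene association table to its
#' approved form, following the authority table's precedence: a symbol that
#' is itself approved stays; otherwise a hit among previous symbols wins
#' over a hit among aliases; symbols matching nothing are dropped.
#' Withdrawn records never receive mappings. Duplicate associations created
#' by rewriting are merged (set semantics).
#'
#' @param assocs data.frame with columns `code`, `gene` (as from
#'   [read_mapping_table()] with schema `"disease_gene"`).
#' @param authority data.frame with columns `approved`, `previous`,
#'   `aliases` ('|'-joined), `status` (schema `"hgnc"`).
#' @return list with elements `assocs` (normalized, deduplicated
#'   associations) and `report` (a `normalization_report`: input rows, rows
#'   already approved, rows mapped via previous/alias, rows dropped as
#'   unmatched, rows merged by deduplication).
#' @details A raw symbol listed as previous/alias of two different approved
#'   records at its best matching tier raises a classified ambiguity error
#'   rather than guessing. The operation is idempotent: approved output
#'   symbols map to themselves on a second pass.
#' @export
#' @examples
#' auth <- data.frame(approved = "EGFR", previous = "ERBB1", aliases = "",
#'                    status = "approved")
#' assocs <- data.frame(code = "C34", gene = "ERBB1")
#' normalize_symbols(assocs, auth)$assocs
normalize_symbols <- function(assocs, authority) {
  stopifnot(all(c("code", "gene") %in% names(assocs)),
            all(c("approved", "previous", "aliases", "status") %in%
                  names(authority)))
  act <- authority[authority$status == "approved", , drop = FALSE]
  if (anyDuplicated(act$approved)) {
    dz_error("diseasome_parse_error",
             "authority table has duplicate approved symbols")
  }
  split_multi <- function(s) {
    p <- strsplit(s, "|", fixed = TRUE)
    lapply(p, function(v) v[nzchar(v)])
  }
  prev_l <- split_multi(act$previous)
  alias_l <- split_multi(act$aliases)
  prev_map <- data.frame(
    raw = unlist(prev_l),
    target = rep(act$approved, lengths(prev_l)),
    stringsAsFactors = FALSE)
  alias_map <- data.frame(
    raw = unlist(alias_l),
    target = rep(act$approved, lengths(alias_l)),
    stringsAsFactors = FALSE)

  resolve <- function(sym) {
    if (sym %in% act$approved) return(sym)
    for (map in list(prev_map, alias_map)) {
      hits <- unique(map$target[map$raw == sym])
      if (length(hits) == 1L) return(hits)
      if (length(hits) > 1L) {
        dz_error("diseasome_ambiguous_symbol",
                 sprintf("symbol '%s' maps to multiple approved records: %s",
                         sym, paste(sort(hits), collapse = ", ")),
                 symbol = sym, candidates = sort(hits))
      }
    }
    NA_character_
  }

  raw_syms <- unique(assocs$gene)
  resolved <- vapply(raw_syms, resolve, character(1))
  mapped_to <- resolved[assocs$gene]

  n_input <- nrow(assocs)
  already <- !is.na(mapped_to) & mapped_to == assocs$gene
  via_map <- !is.na(mapped_to) & mapped_to != assocs$gene
  dropped <- is.na(mapped_to)

  kept <- data.frame(code = assocs$code[!dropped],
                     gene = unname(mapped_to[!dropped]),
                     stringsAsFactors = FALSE)
  before <- nrow(kept)
  kept <- unique(kept)
  kept <- kept[order(kept$code, kept$gene), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "schema") <- "disease_gene"

  report <- structure(list(
    n_input_rows = n_input,
    n_already_approved = sum(already),
    n_mapped_via_previous_or_alias = sum(via_map),
    n_dropped_unmatched = sum(dropped),
    n_deduplicated = before - nrow(kept)
  ), class = "normalization_report")

  list(assocs = kept, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("Gene symbol normalization report\n")
  cat(sprintf("  input rows:                %d\n", x$n_input_rows))
  cat(sprintf("  already approved:          %d\n", x$n_already_approved))
  cat(sprintf("  mapped via previous/alias: %d\n",
              x$n_mapped_via_previous_or_alias))
  cat(sprintf("  dropped (unmatched):       %d\n", x$n_dropped_unmatched))
  cat(sprintf("  merged by deduplication:   %d\n", x$n_deduplicated))
  invisible(x)
}

#' Write a normalization report as JSON
#'
#' @param report a `normalization_report` from [normalize_symbols()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normalization_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
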