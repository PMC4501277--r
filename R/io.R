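## Readers/writers for the four tab-separated mapping tables.
## All tables carry a header row; multi-symbol cells in the authority
## table are '|'-separated. Malformed rows raise a classified parse
## error naming the offending line numbers (header = line 1).

.SCHEMAS <- list(
  disease_gene = c("icd10cm_code", "gene_symbol"),
  gene_pathway = c("gene_symbol", "pathway_id"),
  hgnc = c("approved_symbol", "previous_symbols", "alias_symbols", "status"),
  chapters = c("range", "name")
)

#' Read a standardized mapping table
#'
#' Reads one of the four tab-separated mapping tables used by the pipeline:
#' disease-gene associations, gene-pathway memberships, the gene-symbol
#' authority table, or the ICD chapter table. Codes and symbols are
#' normalized to uppercase on read; duplicate association rows are dropped
#' (set semantics) and counted in the `"n_duplicates"` attribute.
#'
#' @param path path to a TSV file with a header row.
#' @param schema one of `"disease_gene"`, `"gene_pathway"`, `"hgnc"`,
#'   `"chapters"`.
#' @return a data.frame of typed records:
#'   `disease_gene` has columns `code`, `gene`; `gene_pathway` has `gene`,
#'   `pathway`; `hgnc` has `approved`, `previous`, `aliases` ('|'-joined),
#'   `status`; `chapters` has `range`, `name`, `start`, `end`.
#' @export
read_mapping_table <- function(path,
                               schema = c("disease_gene", "gene_pathway",
                                          "hgnc", "chapters")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    dz_error("diseasome_io_error", sprintf("file not found: %s", path))
  }
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", na.strings = NULL)
  req <- .SCHEMAS[[schema]]
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    dz_error("diseasome_parse_error",
             sprintf("%s table is missing column(s): %s",
                     schema, paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, req, drop = FALSE]
  lines <- seq_len(nrow(raw)) + 1L  # data line numbers incl. header offset

  fail <- function(which_bad, what) {
    dz_error("diseasome_parse_error",
             sprintf("%s in %s table at line(s): %s",
                     what, schema, paste(lines[which_bad], collapse = ", ")),
             lines = lines[which_bad])
  }

  out <- switch(schema,
    disease_gene = {
      code <- normalize_icd_code(raw$icd10cm_code)
      gene <- normalize_gene_symbol(raw$gene_symbol)
      if (anyNA(code)) fail(is.na(code), "malformed ICD-10-CM code")
      if (anyNA(gene)) fail(is.na(gene), "malformed gene symbol")
      data.frame(code = code, gene = gene, stringsAsFactors = FALSE)
    },
    gene_pathway = {
      gene <- normalize_gene_symbol(raw$gene_symbol)
      pw <- validate_pathway_id(raw$pathway_id)
      if (anyNA(gene)) fail(is.na(gene), "malformed gene symbol")
      if (anyNA(pw)) fail(is.na(pw), "malformed pathway identifier")
      data.frame(gene = gene, pathway = pw, stringsAsFactors = FALSE)
    },
    hgnc = {
      appr <- normalize_gene_symbol(raw$approved_symbol)
      if (anyNA(appr)) fail(is.na(appr), "malformed approved symbol")
      status <- tolower(trimws(raw$status))
      bad_status <- !status %in% c("approved", "withdrawn")
      if (any(bad_status)) fail(bad_status, "unknown status")
      norm_multi <- function(cell) {
        parts <- unlist(strsplit(cell, "|", fixed = TRUE))
        parts <- parts[nzchar(trimws(parts))]
        if (length(parts) == 0) return("")
        parts <- normalize_gene_symbol(parts)
        if (anyNA(parts)) return(NA_character_)
        paste(sort(unique(parts)), collapse = "|")
      }
      prev <- vapply(raw$previous_symbols, norm_multi, character(1),
                     USE.NAMES = FALSE)
      alia <- vapply(raw$alias_symbols, norm_multi, character(1),
                     USE.NAMES = FALSE)
      if (anyNA(prev)) fail(is.na(prev), "malformed previous symbol")
      if (anyNA(alia)) fail(is.na(alia), "malformed alias symbol")
      hg <- data.frame(approved = appr, previous = prev, aliases = alia,
                       status = status, stringsAsFactors = FALSE)
      self_ref <- mapply(function(a, p, al) {
        a %in% c(strsplit(p, "|", fixed = TRUE)[[1]],
                 strsplit(al, "|", fixed = TRUE)[[1]])
      }, hg$approved, hg$previous, hg$aliases)
      if (any(self_ref)) {
        fail(self_ref, "approved symbol listed among its own previous/alias symbols")
      }
      hg
    },
    chapters = validate_chapters(
      data.frame(range = toupper(trimws(raw$range)), name = trimws(raw$name),
                 stringsAsFactors = FALSE))
  )

  n_dup <- 0L
  if (schema %in% c("disease_gene", "gene_pathway")) {
    before <- nrow(out)
    out <- unique(out)
    n_dup <- before - nrow(out)
    out <- out[order(out[[1]], out[[2]]), , drop = FALSE]
  }
  if (schema == "hgnc") {
    appr_ok <- out$approved[out$status == "approved"]
    if (anyDuplicated(appr_ok)) {
      dz_error("diseasome_parse_error",
               sprintf("duplicate approved symbol(s): %s",
                       paste(unique(appr_ok[duplicated(appr_ok)]),
                             collapse = ", ")))
    }
  }
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- n_dup
  attr(out, "schema") <- schema
  out
}

#' Write a standardized mapping table
#'
#' Inverse of [read_mapping_table()]: writes a TSV with the schema's header,
#' UTF-8, LF line endings, rows sorted deterministically. Re-reading a
#' written table yields an identical record set.
#'
#' @param x data.frame as returned by [read_mapping_table()] (or with the
#'   same columns).
#' @param path output file path.
#' @param schema table schema; defaults to the `"schema"` attribute of `x`.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(x, path, schema = attr(x, "schema")) {
  if (is.null(schema)) {
    dz_error("diseasome_io_error", "schema not given and not an attribute of x")
  }
  schema <- match.arg(schema, names(.SCHEMAS))
  cols <- switch(schema,
    disease_gene = c(code = "icd10cm_code", gene = "gene_symbol"),
    gene_pathway = c(gene = "gene_symbol", pathway = "pathway_id"),
    hgnc = c(approved = "approved_symbol", previous = "previous_symbols",
             aliases = "alias_symbols", status = "status"),
    chapters = c(range = "range", name = "name")
  )
  out <- x[, names(cols), drop = FALSE]
  names(out) <- unname(cols)
  out <- out[do.call(order, out), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
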