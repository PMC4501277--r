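## Gene-disease prediction by pathway enrichment. For a candidate gene g
## (no known phenotype-causing mutation, >= 1 pathway membership) and a
## disease d, a 2x2 table over the pathway universe is tested with a
## two-tailed Fisher exact test; pairs with p <= alpha are reported,
## ranked by ascending p.

#' Candidate genes for prediction
#'
#' Genes eligible for gene-disease prediction: members of at least one
#' pathway, but absent from the disease-gene association set (no known
#' phenotype-causing mutation).
#'
#' @param gene_profiles named list mapping gene symbol to pathway set.
#' @param disease_genes character vector of genes with known associations.
#' @return sorted character vector of candidate gene symbols.
#' @export
candidate_gene_set <- function(gene_profiles, disease_genes) {
  genes <- names(gene_profiles)[lengths(gene_profiles) > 0]
  sort(setdiff(genes, disease_genes))
}

#' Build the 2x2 enrichment contingency table
#'
#' Two constructions are supported for the table tested by
#' [fisher_two_tailed()]. Writing `a = |N_g ∩ N_d|` (pathways shared by the
#' gene and the disease), `N_g`/`N_d` for the gene's and disease's pathway
#' counts and `N` for the universe size:
#' \describe{
#'   \item{`paper_literal`}{`b = N_g - a`, `c = N_d`, `d = N - N_d`. The
#'     shared pathways are counted in both rows; kept as the default for
#'     fidelity to the published table.}
#'   \item{`conventional`}{`b = N_g - a`, `c = N_d - a`,
#'     `d = N - N_g - N_d + a`: the standard disjoint 2x2 overlap
#'     decomposition.}
#' }
#'
#' @param gene_pathways,disease_pathways character vectors (sets).
#' @param N pathway universe size; must be at least
#'   `|gene_pathways ∪ disease_pathways|`.
#' @param mode `"paper_literal"` (default) or `"conventional"`.
#' @return a `contingency_table`: list with `a`, `b`, `c`, `d`, `N_g`,
#'   `N_d`, `N`, `mode`.
#' @export
contingency_table <- function(gene_pathways, disease_pathways, N,
                              mode = c("paper_literal", "conventional")) {
  mode <- match.arg(mode)
  gene_pathways <- unique(gene_pathways)
  disease_pathways <- unique(disease_pathways)
  n_union <- length(union(gene_pathways, disease_pathways))
  if (N < n_union) {
    dz_error("diseasome_contract_error",
             sprintf("universe size N = %d smaller than |N_g u N_d| = %d",
                     N, n_union))
  }
  a <- length(intersect(gene_pathways, disease_pathways))
  N_g <- length(gene_pathways)
  N_d <- length(disease_pathways)
  b <- N_g - a
  if (mode == "paper_literal") {
    cc <- N_d
    d <- N - N_d
  } else {
    cc <- N_d - a
    d <- N - N_g - N_d + a
    if (min(a, b, cc, d) < 0) {
      dz_error("diseasome_contract_error",
               sprintf(paste0("conventional table has a negative cell: ",
                              "a=%d b=%d c=%d d=%d (N_g=%d N_d=%d N=%d)"),
                       a, b, cc, d, N_g, N_d, N))
    }
  }
  structure(list(a = a, b = b, c = cc, d = d,
                 N_g = N_g, N_d = N_d, N = N, mode = mode),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 enrichment table (%s mode):\n", x$mode))
  print(matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
               dimnames = list(c("pathways in gene", "pathways not in gene"),
                               c("in disease", "not in disease"))))
  cat(sprintf("N_g = %d, N_d = %d, N = %d\n", x$N_g, x$N_d, x$N))
  invisible(x)
}

## two-sided Fisher p for cells (a,b,c,d), log-space hypergeometric sums
fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 < 1) {
    dz_error("diseasome_contract_error", "table total must be >= 1")
  }
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  logp <- dhyper(support, m, n2, k, log = TRUE)
  obs <- dhyper(a, m, n2, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log1p(rel_tol)]))
  min(1, p)
}

#' Two-tailed Fisher exact test
#'
#' Exact two-sided p-value for a 2x2 table: the sum of hypergeometric point
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's point probability (with relative slack
#' `1e-7` for floating-point ties). Computed in log space, so large margins
#' never overflow.
#'
#' @param table a `contingency_table` from [contingency_table()], or a
#'   numeric vector `c(a, b, c, d)` of non-negative cells.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' fisher_two_tailed(c(1, 0, 0, 1))  # 1.0
#' fisher_two_tailed(c(5, 2, 3, 10))
fisher_two_tailed <- function(table) {
  if (inherits(table, "contingency_table")) {
    cells <- c(table$a, table$b, table$c, table$d)
  } else {
    cells <- as.numeric(table)
  }
  if (length(cells) != 4 || anyNA(cells) || any(cells < 0) ||
      any(cells != floor(cells))) {
    dz_error("diseasome_contract_error",
             "table must hold four non-negative integer cells")
  }
  fisher_p(cells[1], cells[2], cells[3], cells[4])
}

#' Predict gene-disease associations by pathway enrichment
#'
#' Evaluates every (candidate gene, disease) pair sharing at least one
#' pathway with a two-tailed Fisher exact test on the 2x2 table of
#' [contingency_table()], keeps pairs with `p <= alpha`, and ranks all
#' evaluated pairs ascending by p (ties broken by descending shared-pathway
#' count, then gene symbol, then disease code — deterministic output).
#'
#' @param candidates named list mapping candidate gene symbol to pathway
#'   set (see [candidate_gene_set()]).
#' @param diseases named list mapping disease code to pathway set (see
#'   [disease_pathway_profiles()]).
#' @param alpha significance threshold in `(0, 1]` on the raw p-value
#'   (default 0.001).
#' @param mode contingency construction, see [contingency_table()].
#' @param universe `"disease_linked"` (default; the universe is the union
#'   of pathways over disease profiles, and candidate profiles are
#'   restricted to it) or `"all"` (union over diseases and candidates).
#' @param N optional explicit universe size overriding `universe`.
#' @param bh if `TRUE`, the `alpha` filter is applied to Benjamini-Hochberg
#'   adjusted p-values instead of raw ones (off by default; the reference
#'   procedure filters raw p).
#' @return an `enrichment_result`: list with `predictions` (kept pairs:
#'   `gene`, `code`, `shared_pathways`, `p_value`, `rank`), `evaluated`
#'   (all ranked pairs), `n_evaluated`, `n_kept`, `universe_size`, `alpha`,
#'   `mode`.
#' @export
enrich_predictions <- function(candidates, diseases, alpha = 0.001,
                               mode = c("paper_literal", "conventional"),
                               universe = c("disease_linked", "all"),
                               N = NULL, bh = FALSE) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  stopifnot(alpha > 0, alpha <= 1)
  empty <- data.frame(gene = character(0), code = character(0),
                      shared_pathways = integer(0), p_value = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  result <- function(kept, evaluated, n_univ) {
    structure(list(predictions = kept, evaluated = evaluated,
                   n_evaluated = nrow(evaluated), n_kept = nrow(kept),
                   universe_size = n_univ, alpha = alpha, mode = mode),
              class = "enrichment_result")
  }
  if (length(candidates) == 0 || length(diseases) == 0) {
    return(result(empty, empty, 0L))
  }
  disease_univ <- sort(unique(unlist(diseases, use.names = FALSE)))
  univ <- if (universe == "disease_linked") disease_univ else
    sort(unique(c(disease_univ, unlist(candidates, use.names = FALSE))))
  if (is.null(N)) N <- length(univ)
  ## restrict profiles to the universe so the 2x2 construction is coherent
  candidates <- lapply(candidates, function(p) intersect(unique(p), univ))
  candidates <- candidates[lengths(candidates) > 0]
  diseases <- lapply(diseases, function(p) intersect(unique(p), univ))
  diseases <- diseases[lengths(diseases) > 0]
  if (length(candidates) == 0 || length(diseases) == 0) {
    return(result(empty, empty, N))
  }
  ## shared-pathway counts via incidence crossproduct
  Mc <- incidence_matrix(candidates, univ)
  Md <- incidence_matrix(diseases, univ)
  S <- tcrossprod(Mc, Md)
  idx <- which(S >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(result(empty, empty, N))
  }
  a <- as.integer(S[idx])
  Ng <- as.integer(rowSums(Mc))[idx[, 1]]
  Nd <- as.integer(rowSums(Md))[idx[, 2]]
  b <- Ng - a
  if (mode == "paper_literal") {
    cc <- Nd
    d <- N - Nd
  } else {
    cc <- Nd - a
    d <- N - Ng - Nd + a
    if (min(d) < 0 || min(cc) < 0) {
      dz_error("diseasome_contract_error",
               "conventional table has a negative cell for some pair")
    }
  }
  ## memoize p over distinct (a, b, c, d) cell patterns
  key <- paste(a, b, cc, d)
  uk <- !duplicated(key)
  pu <- mapply(fisher_p, a[uk], b[uk], cc[uk], d[uk])
  names(pu) <- key[uk]
  p <- unname(pu[key])

  evaluated <- data.frame(
    gene = rownames(Mc)[idx[, 1]],
    code = rownames(Md)[idx[, 2]],
    shared_pathways = a,
    p_value = p,
    stringsAsFactors = FALSE)
  o <- order(evaluated$p_value, -evaluated$shared_pathways,
             evaluated$gene, evaluated$code)
  evaluated <- evaluated[o, , drop = FALSE]
  evaluated$rank <- seq_len(nrow(evaluated))
  rownames(evaluated) <- NULL
  keep_p <- if (bh) p.adjust(evaluated$p_value, method = "BH") else
    evaluated$p_value
  kept <- evaluated[keep_p <= alpha, , drop = FALSE]
  rownames(kept) <- NULL
  result(kept, evaluated, N)
}

incidence_matrix <- function(profiles, universe) {
  M <- matrix(0, nrow = length(profiles), ncol = length(universe),
              dimnames = list(names(profiles), universe))
  ri <- rep(seq_along(profiles), lengths(profiles))
  ci <- match(unlist(profiles, use.names = FALSE), universe)
  M[cbind(ri, ci)] <- 1
  M
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("Pathway enrichment: %d pairs evaluated, %d kept at ",
                     "p <= %g (universe %d pathways, %s table)\n"),
              x$n_evaluated, x$n_kept, x$alpha, x$universe_size, x$mode))
  if (x$n_kept > 0) {
    cat("Top predictions:\n")
    print(utils::head(x$predictions, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Write ranked predictions and a run summary
#'
#' @param result an `enrichment_result`.
#' @param tsv_path path for the ranked TSV
#'   (`gene`, `code`, `shared_pathways`, `p_value`, `rank`).
#' @param summary_path optional path for a JSON run summary (pairs
#'   evaluated, pairs kept, universe size, alpha, mode).
#' @return `tsv_path`, invisibly.
#' @export
write_predictions <- function(result, tsv_path, summary_path = NULL) {
  con <- file(tsv_path, open = "wb")
  write.table(result$predictions, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  close(con)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(pairs_evaluated = result$n_evaluated,
                              pairs_kept = result$n_kept,
                              universe_size = result$universe_size,
                              alpha = result$alpha, mode = result$mode),
                         summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
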