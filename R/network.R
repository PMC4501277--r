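## Bipartite disease-gene network, tripartite code-gene-pathway join,
## element profiles and the disease-pair overlap projection.

#' Build the bipartite disease-gene network
#'
#' Nodes are the distinct ICD-10-CM codes and gene symbols appearing in the
#' association list; edges are the deduplicated associations.
#'
#' @param assocs data.frame with columns `code`, `gene` (normalized to
#'   approved symbols).
#' @return a `bipartite_network`: list with `diseases`, `genes`, `edges`.
#' @export
build_bipartite <- function(assocs) {
  if (nrow(assocs) == 0) {
    edges <- data.frame(code = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- unique(assocs[, c("code", "gene")])
    edges <- edges[order(edges$code, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(diseases = sort(unique(edges$code)),
                 genes = sort(unique(edges$gene)),
                 edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite disease-gene network: %d diseases, %d genes, %d edges\n",
              length(x$diseases), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Per-disease gene profiles
#'
#' Groups the bipartite network's adjacency by disease: one profile per
#' disease node, holding the set of genes linked to it.
#'
#' @param net a `bipartite_network`.
#' @return named list of character vectors (sorted), one per disease with
#'   at least one edge, with attribute `mode = "gene"`.
#' @export
disease_profiles <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  profiles <- lapply(split(net$edges$gene, net$edges$code),
                     function(g) sort(unique(g)))
  profiles <- profiles[order(names(profiles))]
  attr(profiles, "mode") <- "gene"
  profiles
}

#' Build the tripartite code-gene-pathway interaction set
#'
#' Joins disease-gene and gene-pathway associations on the gene: the result
#' is exactly the set of (code, gene, pathway) triples where both component
#' edges exist. Genes lacking either side contribute nothing.
#'
#' @param dg data.frame with columns `code`, `gene`.
#' @param gp data.frame with columns `gene`, `pathway`.
#' @return data.frame with columns `code`, `gene`, `pathway`, deduplicated
#'   and sorted.
#' @export
build_tripartite <- function(dg, gp) {
  dg <- unique(dg[, c("code", "gene")])
  gp <- unique(gp[, c("gene", "pathway")])
  triples <- merge(dg, gp, by = "gene")[, c("code", "gene", "pathway")]
  triples <- unique(triples)
  triples <- triples[order(triples$code, triples$gene, triples$pathway), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  triples
}

#' Per-disease pathway profiles
#'
#' Groups the tripartite interactions by disease code: each profile is the
#' union of pathways over the code's triples.
#'
#' @param triples data.frame from [build_tripartite()].
#' @return named list of sorted character vectors with attribute
#'   `mode = "pathway"`.
#' @export
disease_pathway_profiles <- function(triples) {
  profiles <- lapply(split(triples$pathway, triples$code),
                     function(p) sort(unique(p)))
  profiles <- profiles[order(names(profiles))]
  attr(profiles, "mode") <- "pathway"
  profiles
}

#' Project disease-pair overlaps from element profiles
#'
#' Links two diseases whenever their element profiles (genes or pathways)
#' intersect, carrying the shared element set. Pairs are unordered and
#' stored with the lexicographically smaller code first; diseases with
#' empty profiles are excluded.
#'
#' @param profiles named list of element sets, with attribute `mode`
#'   (`"gene"` or `"pathway"`), as produced by [disease_profiles()] or
#'   [disease_pathway_profiles()].
#' @return data.frame with columns `x`, `y`, `n_shared` and a list column
#'   `shared` (the shared element sets); attribute `mode` carried over.
#' @export
project_disease_pairs <- function(profiles) {
  mode <- attr(profiles, "mode")
  if (is.null(mode) || !mode %in% c("gene", "pathway")) {
    dz_error("diseasome_contract_error",
             "profiles must carry a single mode ('gene' or 'pathway')")
  }
  profiles <- profiles[lengths(profiles) > 0]
  profiles <- profiles[order(names(profiles))]
  empty <- data.frame(x = character(0), y = character(0),
                      n_shared = integer(0), stringsAsFactors = FALSE)
  empty$shared <- list()
  if (length(profiles) < 2) {
    attr(empty, "mode") <- mode
    return(empty)
  }
  ## inverted index: every element names the diseases carrying it; each
  ## disease pair within that group shares the element
  long <- data.frame(
    disease = rep(seq_along(profiles), lengths(profiles)),
    element = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE)
  by_elem <- split(long$disease, long$element)
  by_elem <- by_elem[lengths(by_elem) >= 2]
  if (length(by_elem) == 0) {
    attr(empty, "mode") <- mode
    return(empty)
  }
  xs <- vector("list", length(by_elem))
  ys <- vector("list", length(by_elem))
  el <- vector("list", length(by_elem))
  for (k in seq_along(by_elem)) {
    d <- sort(by_elem[[k]])
    cb <- utils::combn(d, 2L)
    xs[[k]] <- cb[1L, ]
    ys[[k]] <- cb[2L, ]
    el[[k]] <- rep(names(by_elem)[k], ncol(cb))
  }
  xi <- unlist(xs); yi <- unlist(ys); ev <- unlist(el)
  key <- paste0(xi, "_", yi)
  shared <- split(ev, key)
  first <- !duplicated(key)
  kx <- xi[first]; ky <- yi[first]; kk <- key[first]
  o <- order(kx, ky)
  kx <- kx[o]; ky <- ky[o]; kk <- kk[o]
  shared <- shared[kk]
  shared <- lapply(shared, sort)
  pairs <- data.frame(x = names(profiles)[kx], y = names(profiles)[ky],
                      n_shared = lengths(shared), stringsAsFactors = FALSE)
  pairs$shared <- unname(shared)
  rownames(pairs) <- NULL
  attr(pairs, "mode") <- mode
  pairs
}

#' Export a network to an edge list or GraphML
#'
#' Writes a bipartite disease-gene network or a disease-pair projection as
#' either a TSV edge list or GraphML. For projections the edge weight is
#' the raw shared-element count; bipartite edge lists carry node-type
#' columns. Output is UTF-8, LF line endings, deterministically sorted.
#'
#' @param x a `bipartite_network` or a pairs data.frame from
#'   [project_disease_pairs()].
#' @param path output file path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  is_pairs <- is.data.frame(x) && all(c("x", "y", "n_shared") %in% names(x))
  if (!is_pairs && !inherits(x, "bipartite_network")) {
    dz_error("diseasome_contract_error",
             "x must be a bipartite_network or a disease-pair projection")
  }
  if (format == "edge_list_tsv") {
    if (is_pairs) {
      out <- data.frame(source = x$x, target = x$y, weight = x$n_shared,
                        stringsAsFactors = FALSE)
    } else {
      out <- data.frame(source = x$edges$code, target = x$edges$gene,
                        source_type = "disease", target_type = "gene",
                        stringsAsFactors = FALSE)
    }
    out <- out[order(out$source, out$target), , drop = FALSE]
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
  } else {
    g <- as_igraph(x)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert to an igraph object
#'
#' @param x a `bipartite_network` (vertices get a `type` attribute,
#'   `"disease"`/`"gene"`) or a disease-pair projection (edges get a
#'   `weight` attribute equal to the shared-element count).
#' @return an igraph graph.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "bipartite_network")) {
    verts <- data.frame(
      name = c(x$diseases, x$genes),
      type = rep(c("disease", "gene"),
                 c(length(x$diseases), length(x$genes))),
      stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
      data.frame(from = x$edges$code, to = x$edges$gene),
      directed = FALSE, vertices = verts)
  } else if (is.data.frame(x) && all(c("x", "y", "n_shared") %in% names(x))) {
    igraph::graph_from_data_frame(
      data.frame(from = x$x, to = x$y, weight = x$n_shared),
      directed = FALSE)
  } else {
    dz_error("diseasome_contract_error", "cannot convert x to igraph")
  }
}
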