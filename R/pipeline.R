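#' Run the full association pipeline on a set of mapping tables
#'
#' Convenience wrapper chaining the whole analysis: normalize gene symbols
#' against the authority table, build the bipartite disease-gene network
#' and its gene-sharing pair projection, join in pathways to form the
#' tripartite interaction set and the pathway-sharing projection, compute
#' directed inclusion records in both modes, and (optionally) run pathway
#' enrichment for candidate genes with no known disease association.
#'
#' @param tables list with elements `hgnc`, `disease_gene`, `gene_pathway`,
#'   `chapters` — as returned by [generate_study()] or assembled from
#'   [read_mapping_table()] calls. A `synthetic_study` works directly.
#' @param alpha enrichment threshold on the raw p-value.
#' @param mode contingency construction for enrichment.
#' @param universe pathway universe rule for enrichment.
#' @param enrich if `FALSE`, skip the enrichment stage.
#' @return list with `normalized`, `report`, `bipartite`, `gene_profiles`,
#'   `gene_pairs`, `triples`, `pathway_profiles`, `pathway_pairs`,
#'   `inclusion_gene`, `inclusion_pathway`, `enrichment` (or `NULL`),
#'   `study_id` (when the input carried one).
#' @export
#' @examples
#' study <- generate_study(synthetic_config(seed = 7, codes_per_chapter = 3,
#'                                          n_genes = 200, n_pathways = 60,
#'                                          n_background_candidates = 40))
#' res <- run_study_pipeline(study)
#' res$bipartite
run_study_pipeline <- function(tables, alpha = 0.001,
                               mode = c("paper_literal", "conventional"),
                               universe = c("disease_linked", "all"),
                               enrich = TRUE) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  norm <- normalize_symbols(tables$disease_gene, tables$hgnc)
  net <- build_bipartite(norm$assocs)
  gene_profiles <- disease_profiles(net)
  gene_pairs <- project_disease_pairs(gene_profiles)
  incl_gene <- all_directed_inclusions(gene_profiles, gene_pairs)

  triples <- build_tripartite(norm$assocs, tables$gene_pathway)
  pw_profiles <- disease_pathway_profiles(triples)
  pw_pairs <- project_disease_pairs(pw_profiles)
  incl_pw <- all_directed_inclusions(pw_profiles, pw_pairs)

  enrichment <- NULL
  if (enrich) {
    gp <- unique(tables$gene_pathway[, c("gene", "pathway")])
    all_gene_pw <- lapply(split(gp$pathway, gp$gene),
                          function(p) sort(unique(p)))
    cand <- candidate_gene_set(all_gene_pw, net$genes)
    enrichment <- enrich_predictions(all_gene_pw[cand], pw_profiles,
                                     alpha = alpha, mode = mode,
                                     universe = universe)
  }

  list(normalized = norm$assocs, report = norm$report,
       bipartite = net, gene_profiles = gene_profiles,
       gene_pairs = gene_pairs, triples = triples,
       pathway_profiles = pw_profiles, pathway_pairs = pw_pairs,
       inclusion_gene = incl_gene, inclusion_pathway = incl_pw,
       enrichment = enrichment,
       study_id = if (!is.null(tables$study_id)) tables$study_id else NULL)
}
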