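## Seeded synthetic study generator. Emits the four mapping tables the
## pipeline consumes (symbol authority, disease-gene, gene-pathway,
## chapters) with planted statistical structure: chapter-clustered gene
## sharing, subset disease pairs (profile(X) strictly inside profile(Y)),
## and candidate genes enriched for a target disease's pathway profile —
## plus machine-readable ground truth for every planted claim.

#' Configuration for a synthetic study
#'
#' Validates and freezes the parameters of [generate_study()]. Defaults
#' describe a mid-sized study: all 21 ICD-10-CM chapters, within-chapter
#' gene sharing much more likely than cross-chapter sharing, small
#' per-gene pathway memberships.
#'
#' @param seed integer seed; one stream drives every table.
#' @param n_chapters number of chapters used (first `n_chapters` of the 21).
#' @param codes_per_chapter synthetic 3-character codes drawn inside each
#'   chapter's range.
#' @param n_genes size of the approved-symbol gene pool.
#' @param genes_per_disease integer range `c(min, max)` of genes drawn per
#'   disease.
#' @param p_within probability a gene draw comes from the disease's own
#'   chapter pool (drives same-chapter sharing).
#' @param p_between probability a draw comes from another chapter's pool;
#'   must be smaller than `p_within`.
#' @param n_subset_pairs planted disease pairs with
#'   `profile(X) ⊂ profile(Y)`.
#' @param n_pathways pathway universe size (ids split over classes
#'   ko / M / H).
#' @param pathways_per_gene integer range of pathway memberships per gene.
#' @param n_planted_enriched planted enriched candidate gene-disease pairs.
#' @param planted_overlap fraction in `(0, 1]` of the target disease's
#'   pathway profile covered by each planted candidate gene.
#' @param alias_rate fraction of disease-linked genes written under a
#'   previous/alias symbol in the disease-gene table.
#' @param n_background_candidates candidate genes with uniformly drawn
#'   pathway sets and no planted signal.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chapters = 21L,
                             codes_per_chapter = 10L,
                             n_genes = 1000L,
                             genes_per_disease = c(2L, 8L),
                             p_within = 0.3,
                             p_between = 0.02,
                             n_subset_pairs = 5L,
                             n_pathways = 300L,
                             pathways_per_gene = c(1L, 6L),
                             n_planted_enriched = 10L,
                             planted_overlap = 0.8,
                             alias_rate = 0.1,
                             n_background_candidates = 200L) {
  cfg <- list(seed = as.integer(seed), n_chapters = as.integer(n_chapters),
              codes_per_chapter = as.integer(codes_per_chapter),
              n_genes = as.integer(n_genes),
              genes_per_disease = as.integer(genes_per_disease),
              p_within = p_within, p_between = p_between,
              n_subset_pairs = as.integer(n_subset_pairs),
              n_pathways = as.integer(n_pathways),
              pathways_per_gene = as.integer(pathways_per_gene),
              n_planted_enriched = as.integer(n_planted_enriched),
              planted_overlap = planted_overlap,
              alias_rate = alias_rate,
              n_background_candidates = as.integer(n_background_candidates))
  fail <- function(msg) dz_error("diseasome_config_error", msg)
  if (cfg$n_chapters < 1 || cfg$n_chapters > 21) {
    fail("n_chapters must be in 1..21")
  }
  if (cfg$codes_per_chapter < 1) fail("codes_per_chapter must be >= 1")
  if (length(cfg$genes_per_disease) != 2 ||
      cfg$genes_per_disease[1] < 1 ||
      cfg$genes_per_disease[1] > cfg$genes_per_disease[2]) {
    fail("genes_per_disease must be an increasing range c(min, max), min >= 1")
  }
  if (cfg$genes_per_disease[2] > cfg$n_genes) {
    fail("genes_per_disease upper bound exceeds n_genes")
  }
  if (!(cfg$p_within > cfg$p_between)) fail("p_within must exceed p_between")
  if (cfg$p_within + cfg$p_between > 1) fail("p_within + p_between must be <= 1")
  if (cfg$planted_overlap <= 0 || cfg$planted_overlap > 1) {
    fail("planted_overlap must lie in (0, 1]")
  }
  if (cfg$alias_rate < 0 || cfg$alias_rate > 1) {
    fail("alias_rate must lie in [0, 1]")
  }
  if (length(cfg$pathways_per_gene) != 2 ||
      cfg$pathways_per_gene[1] < 1 ||
      cfg$pathways_per_gene[1] > cfg$pathways_per_gene[2] ||
      cfg$pathways_per_gene[2] > cfg$n_pathways) {
    fail("pathways_per_gene must be a range within 1..n_pathways")
  }
  n_codes <- cfg$n_chapters * cfg$codes_per_chapter
  if (2L * cfg$n_subset_pairs > n_codes) {
    fail("n_subset_pairs needs two distinct codes per pair")
  }
  if (min(cfg$n_subset_pairs, cfg$n_pathways, cfg$n_planted_enriched,
          cfg$n_background_candidates) < 0) {
    fail("counts must be non-negative")
  }
  structure(cfg, class = "synthetic_config")
}

## draw k distinct synthetic 3-char codes uniformly inside a chapter range
sample_codes_in_range <- function(start, end, k) {
  lo <- icd_block_rank(start)
  hi <- icd_block_rank(end)
  if (hi - lo + 1 < k) {
    dz_error("diseasome_config_error",
             sprintf("chapter %s-%s has fewer than %d codes", start, end, k))
  }
  ranks <- sample(seq(lo, hi), k)
  alphabet <- c(as.character(0:9), LETTERS)
  vapply(ranks, function(r) {
    paste0(LETTERS[r %/% 1296L + 1L],
           alphabet[(r %% 1296L) %/% 36L + 1L],
           alphabet[r %% 36L + 1L])
  }, character(1))
}

#' Generate a synthetic study
#'
#' Produces the four mapping tables plus ground truth, deterministically
#' from `config$seed`. Diseases draw genes preferentially from their own
#' chapter's gene pool (probability `p_within`), occasionally from another
#' chapter's pool (`p_between`), otherwise from a background pool — so
#' same-chapter diseases overlap more than cross-chapter ones. Subset
#' pairs are planted by copying X's gene set into Y and giving Y at least
#' one extra gene. Planted candidate genes never appear in the
#' disease-gene table; each carries a pathway set covering
#' `planted_overlap` of its target disease's pathway profile (targets are
#' drawn among diseases with at least 8 profile pathways so the planted
#' signal is well defined). A fraction `alias_rate` of disease-linked
#' genes is written under a previous or alias symbol, recoverable through
#' [normalize_symbols()].
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_study`: list with `hgnc`, `disease_gene` (raw,
#'   pre-normalization symbols), `gene_pathway`, `chapters`, `truth`
#'   (list: `subset_pairs`, `enriched_pairs`, `alias_map`), `config`,
#'   `study_id`.
#' @export
generate_study <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(config$seed)
  chapters <- icd10_chapters()[seq_len(config$n_chapters), , drop = FALSE]

  codes <- character(0)
  code_chapter <- character(0)
  for (i in seq_len(nrow(chapters))) {
    cs <- sample_codes_in_range(chapters$start[i], chapters$end[i],
                                config$codes_per_chapter)
    codes <- c(codes, cs)
    code_chapter <- c(code_chapter, rep(chapters$range[i], length(cs)))
  }
  names(code_chapter) <- codes

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  ## gene pools: half the pool is split across chapters (drives sharing),
  ## half is background
  shuffled <- sample(genes)
  n_pool <- floor(config$n_genes / 2)
  pool_genes <- shuffled[seq_len(n_pool)]
  background_pool <- shuffled[-seq_len(n_pool)]
  chapter_pool <- split(pool_genes,
                        rep_len(seq_len(config$n_chapters), n_pool))
  names(chapter_pool) <- chapters$range

  draw_profile <- function(ch) {
    k <- sample(seq(config$genes_per_disease[1], config$genes_per_disease[2]),
                1)
    src <- runif(k)
    out <- character(k)
    for (j in seq_len(k)) {
      pool <- if (src[j] < config$p_within) {
        chapter_pool[[ch]]
      } else if (src[j] < config$p_within + config$p_between &&
                 config$n_chapters > 1) {
        chapter_pool[[sample(setdiff(names(chapter_pool), ch), 1)]]
      } else {
        background_pool
      }
      out[j] <- pool[sample.int(length(pool), 1)]
    }
    sort(unique(out))
  }

  profiles <- lapply(codes, function(cd) draw_profile(code_chapter[[cd]]))
  names(profiles) <- codes

  ## plant subset pairs: profile(Y) = profile(X) u {>=1 extra gene}
  subset_pairs <- data.frame(x = character(0), y = character(0),
                             stringsAsFactors = FALSE)
  if (config$n_subset_pairs > 0) {
    chosen <- sample(codes, 2L * config$n_subset_pairs)
    xs <- chosen[seq_len(config$n_subset_pairs)]
    ys <- chosen[-seq_len(config$n_subset_pairs)]
    for (i in seq_len(config$n_subset_pairs)) {
      extra_pool <- setdiff(genes, profiles[[xs[i]]])
      n_extra <- min(length(extra_pool), sample(1:2, 1))
      profiles[[ys[i]]] <- sort(union(profiles[[xs[i]]],
                                      sample(extra_pool, n_extra)))
    }
    subset_pairs <- data.frame(x = xs, y = ys, stringsAsFactors = FALSE)
  }

  dg <- data.frame(
    code = rep(names(profiles), lengths(profiles)),
    gene = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE)

  ## pathway universe over the three identifier classes
  n_ko <- ceiling(config$n_pathways * 0.6)
  n_m <- floor(config$n_pathways * 0.2)
  n_h <- config$n_pathways - n_ko - n_m
  pathways <- c(sprintf("ko%05d", seq_len(n_ko)),
                if (n_m > 0) sprintf("M%05d", seq_len(n_m)),
                if (n_h > 0) sprintf("H%05d", seq_len(n_h)))

  draw_pathways <- function() {
    k <- sample(seq(config$pathways_per_gene[1],
                    config$pathways_per_gene[2]), 1)
    sort(sample(pathways, k))
  }

  used_genes <- sort(unique(dg$gene))
  gene_pw <- lapply(used_genes, function(g) draw_pathways())
  names(gene_pw) <- used_genes

  ## disease pathway profiles implied by the tables, for planting
  dz_pw <- lapply(profiles, function(gs) {
    sort(unique(unlist(gene_pw[gs], use.names = FALSE)))
  })

  ## planted enriched candidates target diseases with a rich enough profile
  enriched_pairs <- data.frame(gene = character(0), code = character(0),
                               stringsAsFactors = FALSE)
  planted_pw <- list()
  if (config$n_planted_enriched > 0) {
    eligible <- names(dz_pw)[lengths(dz_pw) >= 8]
    if (length(eligible) == 0) {
      dz_error("diseasome_config_error",
               "no disease has >= 8 profile pathways to plant enrichment into")
    }
    targets <- sample(eligible, config$n_planted_enriched,
                      replace = config$n_planted_enriched > length(eligible))
    planted_genes <- sprintf("CANDP%04d", seq_len(config$n_planted_enriched))
    planted_pw <- lapply(targets, function(cd) {
      prof <- dz_pw[[cd]]
      sort(sample(prof, ceiling(config$planted_overlap * length(prof))))
    })
    names(planted_pw) <- planted_genes
    enriched_pairs <- data.frame(gene = planted_genes, code = targets,
                                 stringsAsFactors = FALSE)
  }

  background_cand <- list()
  if (config$n_background_candidates > 0) {
    bg_genes <- sprintf("CANDB%05d", seq_len(config$n_background_candidates))
    background_cand <- lapply(bg_genes, function(g) draw_pathways())
    names(background_cand) <- bg_genes
  }

  gp_all <- c(gene_pw, planted_pw, background_cand)
  gp <- data.frame(
    gene = rep(names(gp_all), lengths(gp_all)),
    pathway = unlist(gp_all, use.names = FALSE),
    stringsAsFactors = FALSE)

  ## aliases: some disease-linked genes appear under an older symbol
  n_alias <- round(config$alias_rate * length(used_genes))
  aliased <- if (n_alias > 0) sample(used_genes, n_alias) else character(0)
  alias_map <- character(0)
  hgnc <- data.frame(approved = names(gp_all),
                     previous = "", aliases = "", status = "approved",
                     stringsAsFactors = FALSE)
  if (n_alias > 0) {
    raw_syms <- sub("^G", "ALS", aliased)
    alias_map <- stats::setNames(aliased, raw_syms)
    ## half recorded as previous symbols, half as aliases
    as_prev <- seq_along(aliased) %% 2L == 1L
    hi <- match(aliased, hgnc$approved)
    hgnc$previous[hi[as_prev]] <- raw_syms[as_prev]
    hgnc$aliases[hi[!as_prev]] <- raw_syms[!as_prev]
    dg$gene <- ifelse(dg$gene %in% aliased,
                      raw_syms[match(dg$gene, aliased)], dg$gene)
  }
  ## a couple of withdrawn records exercising the unmatched path
  hgnc <- rbind(hgnc,
                data.frame(approved = c("WDRWN1", "WDRWN2"),
                           previous = "", aliases = "",
                           status = "withdrawn", stringsAsFactors = FALSE))
  hgnc <- hgnc[order(hgnc$approved), , drop = FALSE]

  dg <- unique(dg[order(dg$code, dg$gene), , drop = FALSE])
  gp <- unique(gp[order(gp$gene, gp$pathway), , drop = FALSE])
  rownames(dg) <- rownames(gp) <- rownames(hgnc) <- NULL
  attr(dg, "schema") <- "disease_gene"
  attr(gp, "schema") <- "gene_pathway"
  attr(hgnc, "schema") <- "hgnc"
  chap_tab <- chapters[, c("range", "name", "start", "end")]
  attr(chap_tab, "schema") <- "chapters"

  study_id <- sprintf("synthetic-%d-%d-%d-%d", config$seed,
                      config$n_chapters * config$codes_per_chapter,
                      config$n_genes, config$n_pathways)
  structure(list(
    hgnc = hgnc, disease_gene = dg, gene_pathway = gp, chapters = chap_tab,
    truth = list(subset_pairs = subset_pairs,
                 enriched_pairs = enriched_pairs,
                 alias_map = alias_map,
                 study_id = study_id),
    config = config, study_id = study_id
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study %s: %d codes, %d disease-gene rows, ",
                     "%d gene-pathway rows\n"),
              x$study_id, length(unique(x$disease_gene$code)),
              nrow(x$disease_gene), nrow(x$gene_pathway)))
  cat(sprintf("  planted: %d subset pairs, %d enriched pairs, %d aliases\n",
              nrow(x$truth$subset_pairs), nrow(x$truth$enriched_pairs),
              length(x$truth$alias_map)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the four TSV tables plus `ground_truth.json` into a directory.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mapping_table(study$hgnc, file.path(dir, "hgnc.tsv"), "hgnc")
  write_mapping_table(study$disease_gene, file.path(dir, "disease_gene.tsv"),
                      "disease_gene")
  write_mapping_table(study$gene_pathway, file.path(dir, "gene_pathway.tsv"),
                      "gene_pathway")
  write_mapping_table(study$chapters, file.path(dir, "chapters.tsv"),
                      "chapters")
  jsonlite::write_json(
    list(study_id = study$study_id,
         subset_pairs = study$truth$subset_pairs,
         enriched_pairs = study$truth$enriched_pairs,
         alias_map = as.list(study$truth$alias_map)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score predictions against planted ground truth
#'
#' Compares an enrichment result with the generator's planted enriched
#' pairs: recall at the result's alpha, the planted pairs' median rank on
#' the full evaluated list, and the rank below which the best 5% of
#' non-planted (background) pairs fall.
#'
#' @param result an `enrichment_result` from [enrich_predictions()].
#' @param truth the `truth` element of a `synthetic_study` (or the study
#'   itself).
#' @param study_id optional study identifier carried by the predictions;
#'   if both this and the truth's identifier are present they must match.
#' @return list with `recall_at_alpha`, `n_planted`, `n_planted_kept`,
#'   `median_planted_rank`, `background_rank_q05` (5th percentile of
#'   background ranks; planted pairs outrank the background when their
#'   median rank is at or below it), `planted_outrank_background`.
#' @export
measure_against_truth <- function(result, truth, study_id = NULL) {
  if (inherits(truth, "synthetic_study")) truth <- truth$truth
  if (!is.null(study_id) && !is.null(truth$study_id) &&
      !identical(study_id, truth$study_id)) {
    dz_error("diseasome_integrity_error",
             sprintf("predictions from study '%s' scored against truth '%s'",
                     study_id, truth$study_id))
  }
  planted <- truth$enriched_pairs
  n_planted <- nrow(planted)
  pkey <- paste(planted$gene, planted$code)
  kept_key <- paste(result$predictions$gene, result$predictions$code)
  eval_key <- paste(result$evaluated$gene, result$evaluated$code)
  n_kept <- sum(pkey %in% kept_key)
  recall <- if (n_planted == 0) NA_real_ else n_kept / n_planted
  is_planted <- eval_key %in% pkey
  planted_ranks <- result$evaluated$rank[is_planted]
  background_ranks <- result$evaluated$rank[!is_planted]
  med_planted <- if (length(planted_ranks)) median(planted_ranks) else NA_real_
  bg_q05 <- if (length(background_ranks)) {
    unname(quantile(background_ranks, 0.05, type = 7))
  } else NA_real_
  list(recall_at_alpha = recall,
       n_planted = n_planted,
       n_planted_kept = n_kept,
       median_planted_rank = med_planted,
       background_rank_q05 = bg_q05,
       planted_outrank_background =
         isTRUE(med_planted <= bg_q05))
}
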