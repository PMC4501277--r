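small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, codes_per_chapter = 3, n_genes = 200,
                   n_pathways = 60, n_subset_pairs = 3,
                   n_planted_enriched = 5, n_background_candidates = 30, ...)
}

test_that("the generator is deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(generate_study(small_cfg(seed = 4)), d1)
  write_study(generate_study(small_cfg(seed = 4)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ## a different seed changes the tables
  d3 <- withr::local_tempdir()
  write_study(generate_study(small_cfg(seed = 5)), d3)
  expect_false(identical(readLines(file.path(d1, "disease_gene.tsv")),
                         readLines(file.path(d3, "disease_gene.tsv"))))
})

test_that("infeasible configurations fail validation before any output", {
  expect_error(synthetic_config(genes_per_disease = c(5, 2000), n_genes = 100),
               class = "diseasome_config_error")
  expect_error(synthetic_config(p_within = 0.1, p_between = 0.2),
               class = "diseasome_config_error")
  expect_error(synthetic_config(planted_overlap = 0),
               class = "diseasome_config_error")
  expect_error(synthetic_config(n_subset_pairs = 1000,
                                codes_per_chapter = 2),
               class = "diseasome_config_error")
  expect_error(synthetic_config(pathways_per_gene = c(1, 500),
                                n_pathways = 100),
               class = "diseasome_config_error")
})

test_that("planted subset pairs verify tau = 1 forward and tau < 1 reversed", {
  study <- generate_study(small_cfg(seed = 8))
  res <- run_study_pipeline(study, enrich = FALSE)
  prof <- res$gene_profiles
  truth <- study$truth$subset_pairs
  expect_equal(nrow(truth), 3)
  for (i in seq_len(nrow(truth))) {
    expect_equal(inclusion_index(prof[[truth$x[i]]], prof[[truth$y[i]]]), 1)
    expect_lt(inclusion_index(prof[[truth$y[i]]], prof[[truth$x[i]]]), 1)
  }
  ## the directed records contain the planted tau = 1 pairs
  rec <- res$inclusion_gene
  ones <- rec[rec$tau == 1, ]
  key <- paste(ones$x, ones$y)
  expect_true(all(paste(truth$x, truth$y) %in% key))
  expect_gte(nrow(ones), nrow(truth))
})

test_that("planted enriched pairs share pathways with their target disease", {
  study <- generate_study(small_cfg(seed = 12))
  res <- run_study_pipeline(study, enrich = FALSE)
  gp <- study$gene_pathway
  for (i in seq_len(nrow(study$truth$enriched_pairs))) {
    g <- study$truth$enriched_pairs$gene[i]
    cd <- study$truth$enriched_pairs$code[i]
    gene_pw <- gp$pathway[gp$gene == g]
    expect_gte(length(intersect(gene_pw, res$pathway_profiles[[cd]])), 1)
    ## planted candidates never carry a disease-gene edge
    expect_false(g %in% study$disease_gene$gene)
  }
})

test_that("aliased raw symbols all map back through normalize_symbols", {
  study <- generate_study(small_cfg(seed = 16, alias_rate = 0.2))
  amap <- study$truth$alias_map
  expect_gt(length(amap), 0)
  expect_true(all(names(amap) %in% study$disease_gene$gene))
  norm <- normalize_symbols(study$disease_gene, study$hgnc)
  expect_equal(norm$report$n_dropped_unmatched, 0L)
  expect_true(all(unname(amap) %in% norm$assocs$gene))
  expect_false(any(names(amap) %in% norm$assocs$gene))
})

test_that("same-chapter diseases overlap more than cross-chapter ones", {
  mean_overlap <- function(profiles, same_chapter) {
    nm <- names(profiles)
    chap <- assign_chapter(nm)
    tot <- 0; cnt <- 0
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i < j && (chap[i] == chap[j]) == same_chapter) {
        tot <- tot + length(intersect(profiles[[i]], profiles[[j]]))
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  within <- numeric(10); between <- numeric(10)
  for (s in 1:10) {
    study <- generate_study(synthetic_config(
      seed = s, n_chapters = 5, codes_per_chapter = 8, n_genes = 300,
      n_pathways = 40, p_within = 0.3, p_between = 0.02,
      n_subset_pairs = 0, n_planted_enriched = 0,
      n_background_candidates = 0, alias_rate = 0))
    prof <- disease_profiles(build_bipartite(study$disease_gene))
    within[s] <- mean_overlap(prof, TRUE)
    between[s] <- mean_overlap(prof, FALSE)
  }
  expect_gt(mean(within), mean(between))
})

test_that("emitted tables pass the schema readers cleanly", {
  dir <- withr::local_tempdir()
  write_study(generate_study(small_cfg(seed = 23)), dir)
  expect_silent({
    dg <- read_mapping_table(file.path(dir, "disease_gene.tsv"),
                             "disease_gene")
    gp <- read_mapping_table(file.path(dir, "gene_pathway.tsv"),
                             "gene_pathway")
    hg <- read_mapping_table(file.path(dir, "hgnc.tsv"), "hgnc")
    ch <- read_mapping_table(file.path(dir, "chapters.tsv"), "chapters")
  })
  expect_equal(attr(dg, "n_duplicates"), 0L)
})

test_that("recovery scoring matches hand counts on a fixed fixture", {
  evaluated <- data.frame(
    gene = sprintf("G%d", 1:6), code = rep("C01", 6),
    shared_pathways = 3:8, p_value = c(1e-5, 2e-5, 5e-4, 2e-3, 0.1, 0.5),
    rank = 1:6)
  kept <- evaluated[evaluated$p_value <= 0.001, ]
  result <- structure(list(predictions = kept, evaluated = evaluated,
                           n_evaluated = 6, n_kept = nrow(kept),
                           universe_size = 50, alpha = 0.001,
                           mode = "paper_literal"),
                      class = "enrichment_result")
  truth <- list(enriched_pairs = data.frame(gene = c("G1", "G4"),
                                            code = "C01"))
  rep <- measure_against_truth(result, truth)
  expect_equal(rep$recall_at_alpha, 0.5)   # G1 kept, G4 below threshold
  expect_equal(rep$n_planted_kept, 1)
  expect_equal(rep$median_planted_rank, 2.5)

  empty <- structure(list(predictions = kept[0, ], evaluated = evaluated,
                          n_evaluated = 6, n_kept = 0, universe_size = 50,
                          alpha = 0.001, mode = "paper_literal"),
                     class = "enrichment_result")
  expect_equal(measure_against_truth(empty, truth)$recall_at_alpha, 0)
})

test_that("scoring predictions against the wrong study is an integrity error", {
  study <- generate_study(small_cfg(seed = 2))
  res <- run_study_pipeline(study)
  expect_error(
    measure_against_truth(res$enrichment, study$truth,
                          study_id = "synthetic-999-0-0-0"),
    class = "diseasome_integrity_error")
  ok <- measure_against_truth(res$enrichment, study$truth,
                              study_id = res$study_id)
  expect_equal(ok$recall_at_alpha, 1)
})
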