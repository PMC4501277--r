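test_that("bipartite construction counts distinct endpoints and set-dedups edges", {
  assocs <- data.frame(code = c("C34", "C34", "J45", "J45", "J45"),
                       gene = c("G1", "G2", "G2", "G2", "G2"))
  net <- build_bipartite(assocs)
  expect_equal(length(net$diseases), 2)
  expect_equal(length(net$genes), 2)
  expect_equal(nrow(net$edges), 3)

  empty <- build_bipartite(assocs[0, ])
  expect_equal(length(empty$diseases), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("disease profiles group adjacency and conserve the edge count", {
  net <- build_bipartite(data.frame(code = c("C34", "C34", "J45"),
                                    gene = c("G1", "G2", "G2")))
  prof <- disease_profiles(net)
  expect_equal(prof$C34, c("G1", "G2"))
  expect_equal(prof$J45, "G2")
  expect_equal(attr(prof, "mode"), "gene")
  expect_equal(sum(lengths(prof)), nrow(net$edges))
})

test_that("tripartite join is the exact two-sided composition", {
  dg <- data.frame(code = "C34", gene = "G1")
  gp <- data.frame(gene = c("G1", "G1", "G9"),
                   pathway = c("ko00010", "M00001", "ko00020"))
  tri <- build_tripartite(dg, gp)
  expect_equal(nrow(tri), 2)       # G9 has no disease, contributes nothing
  expect_equal(tri$pathway, c("M00001", "ko00010"))

  ## size identity: sum over genes of deg_dg * deg_gp
  set.seed(42)
  dg2 <- unique(data.frame(code = sample(sprintf("C%02d", 1:10), 40, TRUE),
                           gene = sample(sprintf("G%02d", 1:15), 40, TRUE)))
  gp2 <- unique(data.frame(gene = sample(sprintf("G%02d", 1:20), 50, TRUE),
                           pathway = sample(sprintf("ko%05d", 1:12), 50, TRUE)))
  tri2 <- build_tripartite(dg2, gp2)
  genes <- union(dg2$gene, gp2$gene)
  expected <- sum(vapply(genes, function(g) {
    sum(dg2$gene == g) * sum(gp2$gene == g)
  }, numeric(1)))
  expect_equal(nrow(tri2), expected)
})

test_that("pathway profiles are unions over a disease's triples", {
  tri <- data.frame(code = c("C34", "C34", "C34"),
                    gene = c("G1", "G2", "G2"),
                    pathway = c("ko00010", "ko00010", "M00001"))
  prof <- disease_pathway_profiles(tri)
  expect_equal(prof$C34, c("M00001", "ko00010"))
  expect_equal(attr(prof, "mode"), "pathway")
})

test_that("pair projection matches the hand example and excludes non-overlaps", {
  profiles <- list(D1 = c("g1", "g2"), D2 = c("g2", "g3"), D3 = "g4")
  attr(profiles, "mode") <- "gene"
  pairs <- project_disease_pairs(profiles)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$x, "D1")
  expect_equal(pairs$y, "D2")
  expect_equal(pairs$shared[[1]], "g2")

  single <- profiles[1]
  attr(single, "mode") <- "gene"
  expect_equal(nrow(project_disease_pairs(single)), 0)

  ident <- list(A = c("g1", "g2"), B = c("g1", "g2"), C = c("g1", "g2"),
                D = c("g1", "g2"))
  attr(ident, "mode") <- "gene"
  expect_equal(nrow(project_disease_pairs(ident)), choose(4, 2))
})

test_that("projection requires a declared mode", {
  expect_error(project_disease_pairs(list(A = "g1", B = "g1")),
               class = "diseasome_contract_error")
})

test_that("projection equals the brute-force double loop on random fixtures", {
  set.seed(101)
  for (rep in 1:10) {
    profiles <- random_profiles(n_diseases = sample(5:20, 1),
                                n_elements = 60)
    got <- project_disease_pairs(profiles)
    want <- oracle_project(profiles)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$x, vapply(want, `[[`, "", "x"))
      expect_equal(got$y, vapply(want, `[[`, "", "y"))
      expect_equal(got$shared, lapply(want, `[[`, "shared"))
    }
    ## conservation: every shared element sits in both member profiles
    ok <- mapply(function(x, y, sh) {
      all(sh %in% profiles[[x]]) && all(sh %in% profiles[[y]])
    }, got$x, got$y, got$shared)
    expect_true(all(ok))
    expect_lte(nrow(got), choose(length(profiles), 2))
  }
})

test_that("adding a gene-pathway association never shrinks triples or pairs", {
  set.seed(7)
  dg <- unique(data.frame(code = sample(sprintf("C%02d", 1:8), 30, TRUE),
                          gene = sample(sprintf("G%02d", 1:12), 30, TRUE)))
  gp <- unique(data.frame(gene = sample(sprintf("G%02d", 1:12), 25, TRUE),
                          pathway = sample(sprintf("ko%05d", 1:10), 25, TRUE)))
  base_tri <- build_tripartite(dg, gp)
  base_pairs <- project_disease_pairs(
    disease_pathway_profiles(base_tri))
  for (rep in 1:10) {
    extra <- data.frame(gene = sample(sprintf("G%02d", 1:12), 1),
                        pathway = sample(sprintf("ko%05d", 1:10), 1))
    gp2 <- unique(rbind(gp, extra))
    tri2 <- build_tripartite(dg, gp2)
    pairs2 <- project_disease_pairs(disease_pathway_profiles(tri2))
    expect_gte(nrow(tri2), nrow(base_tri))
    expect_gte(nrow(pairs2), nrow(base_pairs))
  }
})

test_that("edge-list export writes one sorted line per edge with weights", {
  net <- build_bipartite(data.frame(code = c("C34", "C34", "J45"),
                                    gene = c("G1", "G2", "G2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path, "edge_list_tsv")
  lines <- readLines(path)
  expect_length(lines, 1 + nrow(net$edges))
  expect_equal(lines[1], "source\ttarget\tsource_type\ttarget_type")

  pairs <- project_disease_pairs(disease_profiles(net))
  ppath <- withr::local_tempfile(fileext = ".tsv")
  export_network(pairs, ppath, "edge_list_tsv")
  plines <- readLines(ppath)
  expect_equal(plines[2], "C34\tJ45\t1")  # weight = |shared|
})

test_that("graphml export round-trips node and edge sets", {
  net <- build_bipartite(data.frame(code = c("C34", "C34", "J45"),
                                    gene = c("G1", "G2", "G2")))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, c(net$diseases, net$genes))
  el <- igraph::as_edgelist(g)
  got <- apply(apply(el, 1, sort), 2, paste, collapse = "|")
  want <- apply(cbind(net$edges$code, net$edges$gene), 1,
                function(r) paste(sort(r), collapse = "|"))
  expect_setequal(got, want)

  pairs <- project_disease_pairs(disease_profiles(net))
  ppath <- withr::local_tempfile(fileext = ".graphml")
  export_network(pairs, ppath, "graphml")
  gp <- igraph::read_graph(ppath, format = "graphml")
  expect_equal(igraph::E(gp)$weight, pairs$n_shared)
})
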