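Package: diseasome
Title: Disease-Gene-Pathway Networks, Directional Inclusion and
    Gene-Disease Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds disease-gene and disease-gene-pathway networks from
    standardized mapping tables (ICD-10-CM disease codes, HGNC-style gene
    symbol authority, KEGG-style pathway memberships), normalizes gene
    symbols against an authority table, projects disease-pair overlap
    networks, computes the directional inclusion index between disease
    pairs, and predicts new gene-disease associations by two-tailed Fisher
    enrichment over shared pathways. Includes a seeded synthetic-data
    generator with planted subset pairs and planted enriched gene-disease
    pairs so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
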