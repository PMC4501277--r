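---
title: "Disease-gene-pathway networks: inclusion and enrichment methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-gene-pathway networks: inclusion and enrichment methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasome)
```

## The analysis in outline

The package chains five stages. (1) Disease–gene association rows
(ICD-10-CM code, gene symbol) are read and every symbol is normalized
against an HGNC-style authority table, so the rest of the analysis sees
only approved symbols. (2) The associations form a bipartite network;
joining in gene–pathway memberships forms the tripartite set of
(code, gene, pathway) interactions. (3) Projecting either layer links two
diseases whenever their gene (or pathway) profiles intersect. (4) For
every linked pair the directional inclusion index
$\tau_{x \to y} = |X \cap Y| / |X|$ is materialized in both directions.
(5) Genes that belong to pathways but carry no known phenotype-causing
mutation are tested for enrichment against every disease pathway profile
they intersect, with a two-tailed Fisher exact test, and ranked.

The underlying model assumption is guilt by association: diseases with
overlapping molecular repertoires are mechanistically related, and a gene
whose pathway memberships look like a disease's pathway profile is a
candidate for involvement in that disease. The inclusion index adds a
directional refinement — it distinguishes "X's repertoire sits inside
Y's" from mere overlap, which symmetric measures (Jaccard, the
Szymkiewicz–Simpson overlap coefficient, which divides by
$\min(|X|,|Y|)$) cannot express.

## Symbol normalization

Matching precedence is approved > previous > alias: a symbol that is
itself approved is never reinterpreted as someone else's alias, and a hit
among previous symbols suppresses alias hits. This mirrors the
nomenclature authority's own disambiguation convention and makes the
operation deterministic and idempotent. A symbol claimed as
previous/alias by two different approved records at its best tier raises
a classified error rather than guessing. Withdrawn records receive no
mappings; their symbols count as unmatched and the rows are dropped. The
report object records each fate (already approved, rewritten, dropped,
merged by deduplication) so input reductions are auditable.

## Chapter assignment

The shipped chapter table is the standard 21-chapter ICD-10-CM layout,
overridable by any table with `range` and `name` columns. Range
membership uses ICD tabular ordering: the leading letter orders first,
and positions 2–3 order character-wise with digits before letters. This
is the only ordering under which `O9A` lies inside `O00-O9A` (plain
lexicographic ordering puts `O9A` after `O99` but also after `OA0`,
breaking the chapter bounds). Codes falling in the gaps of the standard
layout (`U` codes, `T89`–`T99`) raise a classified "unassignable"
error — deliberately loud, because silently dropping codes would bias
category-level summaries.

## Inclusion analysis choices

Directed records are materialized for both directions of every pair
rather than derived on demand: directionality is the analysis's central
output, and explicit records make the asymmetry directly testable
($\tau_{x\to y} n_x = \tau_{y\to x} n_y = |X \cap Y|$). τ is computed in
floating point; the cross-consistency identity is verified in tests to
1e-12.

Category summaries are five-number summaries with type-7
(linear-interpolation) quartiles — R's default and the common boxplot
convention; the choice is recorded in the output's `quartile_type`
attribute. Same-category summaries pool *directed* records whose two
codes share a chapter; pooling directed rather than undirected values is
a documented choice, since either convention is defensible and the
directed pool is the richer one. No significance test is attached to
directionality differences; the package emits distributions only and
leaves testing to the user.

For a focal chapter (e.g. neoplasms, `C00-D49`), `focal_directionality()`
splits cross-chapter records by the focal code's role (as X: including;
as Y: being included). Records with both codes inside the focal chapter
are excluded — they belong to the same-category view, and mixing them
into the cross-chapter comparison would dilute exactly the contrast the
split is meant to expose.

## Enrichment choices

Two 2×2 constructions are provided. The default, `paper_literal`,
follows the published table verbatim: $c = N_d$, $d = N - N_d$, which
double-counts the shared pathways relative to the standard decomposition.
It is kept as the default for fidelity — "correcting" it silently would
change every p-value. The `conventional` mode ($c = N_d - a$,
$d = N - N_g - N_d + a$) is the textbook disjoint construction; under a
valid universe ($N \ge |N_g \cup N_d|$) its cells are provably
non-negative, and the negative-cell guard is therefore defensive only.

The default universe is the union of pathways linked to diseases, with
`universe = "all"` adding candidate-only pathways. The two definitions
genuinely differ (candidate genes can carry pathways no disease gene
touches), so both are exposed; the disease-linked universe is the
default, and candidate profiles are intersected with the universe before
the table is built so the construction stays coherent. The Fisher
two-sided p sums hypergeometric point probabilities not exceeding the
observed table's, with a 1e-7 relative slack for floating-point ties,
computed in log space so large margins never overflow. Filtering uses
the raw p ≤ α rule (α = 0.001 by default) with no multiple-testing
correction, reproducing the reference procedure; a Benjamini–Hochberg
flag is available but off. Ranks break ties by ascending p, then
descending shared-pathway count, then gene symbol, then code —
arbitrary, but fixed, so identical inputs give byte-identical output.

## What the synthetic generator emulates

One integer seed drives a single random stream for all four tables.
Chapter labels are the real 21 ranges, with synthetic 3-character codes
drawn uniformly inside each range (so the `O9A`-style ordering edge is
exercised). Gene sharing is chapter-clustered: half the gene pool is
partitioned into per-chapter pools and each disease draws from its own
chapter's pool with probability `p_within` (default 0.3), from another
chapter's pool with `p_between` (default 0.02), otherwise from the
background half — same-chapter diseases therefore overlap more, the
structure the category-level summaries assume. Defaults elsewhere:
2–8 genes per disease and 1–6 pathway memberships per gene, which at the
full-scale configuration (21 × 42 codes, 3000 genes, 800 pathways,
5000 candidates) reproduce the order of magnitude of the real networks
(≈4300 associations, ≈15,000 triples, ≈3500 gene-sharing and ≈110,000
pathway-sharing pairs, ≈300,000 evaluated gene–disease pairs).

Planted structure: subset pairs are built by copying X's gene set into Y
plus at least one extra gene, so $\tau_{x\to y} = 1$ and
$\tau_{y\to x} < 1$ hold by construction and their recovery tests the
whole normalize → project → inclusion path. Planted candidate genes
never receive a disease–gene edge (so they always pass the candidate
filter) and carry a pathway set covering `planted_overlap` (default 0.8)
of their target disease's profile; targets are drawn among diseases with
at least 8 profile pathways, because a fraction of a very small profile
is not a meaningful enrichment signal (80 % of a 2-pathway profile is
indistinguishable from background). A configurable fraction of
disease-linked genes is written under a fabricated previous/alias
symbol, recorded in the ground truth's alias map.

What the generator does **not** emulate: real OMIM phenotype text, the
heavy-tailed degree and pathway-size distributions of real KEGG, locus
reclassification histories, or the manual curation that maps phenotypes
to ICD codes. Passing tests therefore show the pipeline's operations are
correct and planted signal is recoverable — not that any biological
conclusion transfers to a particular database snapshot.

## Numerical and degenerate-input conventions

- Empty association lists build empty networks (not errors); projections
  need two non-empty profiles; diseases with empty profiles are excluded
  from projection rather than emitted as isolated nodes.
- The inclusion index over an empty X set is a contract violation
  (division by zero), not NaN.
- Pairs are stored unordered with the lexicographically smaller code
  first; all written outputs are sorted, UTF-8, LF-terminated.
- Projection uses an inverted element index (each element contributes
  the pairs within its carrier set), which is exact and avoids the
  quadratic scan; a brute-force double loop serves as the test oracle.
- Exports carry the raw shared-element count as edge weight, never a
  normalized value.

## Problem sizes in the shipped tests

The test suite runs the oracle equivalences at 6,561 Fisher tables,
1,000 random set pairs and 50 random projection fixtures, recovery
checks at 200–880 diseases across five or more seeds, and one
full-magnitude pipeline run (882 codes / 3000 genes / 800 pathways /
5000 candidates); the whole suite completes in well under a minute on a
single core, and the full-magnitude run takes a few seconds. These sizes
were chosen to exercise the same regimes as the real analyses while
keeping the suite fast to run routinely.

## Known limitations

- The reader expects pre-flattened two-column disease–gene TSVs; native
  OMIM morbid-map syntax (parenthesized mapping keys, comma-separated
  symbol lists) is out of scope because the published reduction of that
  format involved manual curation that cannot be reproduced mechanically.
- No live queries to OMIM/HGNC/KEGG/WHO; no ICD-9↔ICD-10 conversion.
- Exact published counts depend on 2015 database snapshots and a manual
  curation step, and are not reproduction targets; the package
  reproduces the *method* and validates it on planted structure.
- The three pathway classes (ko/M/H) are pooled into one universe with
  no per-class analysis.
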