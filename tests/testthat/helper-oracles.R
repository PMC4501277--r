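# Independent oracles, deliberately written with different machinery than
# the implementation they check.

# Two-sided Fisher p by exhaustive enumeration of all margin-preserving
# tables, point probabilities from choose() ratios (no dhyper, no logs).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pt <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  probs <- vapply(support, pt, numeric(1))
  obs <- pt(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Inclusion index by explicit intersection counting.
oracle_inclusion <- function(x, y) {
  length(intersect(unique(x), unique(y))) / length(unique(x))
}

# Disease-pair projection by brute-force double loop over all pairs.
oracle_project <- function(profiles) {
  nm <- sort(names(profiles))
  out <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) {
        sh <- sort(intersect(profiles[[nm[i]]], profiles[[nm[j]]]))
        if (length(sh) > 0) {
          out[[length(out) + 1]] <- list(x = nm[i], y = nm[j], shared = sh)
        }
      }
    }
  }
  out
}

# Random element profiles for property tests.
random_profiles <- function(n_diseases, n_elements, mode = "gene",
                            max_size = 10) {
  elements <- sprintf("E%04d", seq_len(n_elements))
  profiles <- lapply(seq_len(n_diseases), function(i) {
    sort(sample(elements, sample.int(max_size, 1)))
  })
  names(profiles) <- sprintf("C%02d", seq_len(n_diseases))
  attr(profiles, "mode") <- mode
  profiles
}

# Small curated authority table shared by normalization tests.
fixture_authority <- function() {
  data.frame(
    approved = c("EGFR", "TP53", "BRCA1", "OLD1"),
    previous = c("ERBB1", "", "", ""),
    aliases = c("HER1", "", "RNF53", ""),
    status = c("approved", "approved", "approved", "withdrawn"),
    stringsAsFactors = FALSE)
}
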