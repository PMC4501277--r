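## Directional inclusion analysis. For diseases X and Y with element sets
## (genes or pathways), the inclusion index
##     tau_{x->y} = |X n Y| / |X|,   0 <= tau <= 1,
## measures the degree to which X's elements are contained in Y; tau = 1
## means X is a subset of Y. The index is directional: tau_{x->y} and
## tau_{y->x} share the numerator but divide by different profile sizes.

#' Directional inclusion index between two element sets
#'
#' Computes `|x ∩ y| / |x|`: the fraction of disease X's elements (genes or
#' pathways) contained in disease Y. Not symmetric.
#'
#' @param x_elements,y_elements character vectors (treated as sets).
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' inclusion_index(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))  # 2/3
inclusion_index <- function(x_elements, y_elements) {
  x_elements <- unique(x_elements)
  y_elements <- unique(y_elements)
  if (length(x_elements) == 0) {
    dz_error("diseasome_contract_error",
             "inclusion index undefined for an empty X set")
  }
  sum(x_elements %in% y_elements) / length(x_elements)
}

#' All directed inclusion records for a pair projection
#'
#' Materializes both directions of every unordered disease pair: for a pair
#' (x, y) sharing `s` elements, emits records x→y with `tau = s / n_x` and
#' y→x with `tau = s / n_y`. Record count is exactly twice the pair count.
#'
#' @param profiles named list of element sets (with `mode` attribute) the
#'   pairs were projected from.
#' @param pairs data.frame from [project_disease_pairs()].
#' @return data.frame with columns `x`, `y`, `mode`, `n_x`, `n_y`, `shared`,
#'   `tau`.
#' @export
all_directed_inclusions <- function(profiles, pairs) {
  mode <- attr(profiles, "mode")
  if (is.null(mode)) mode <- attr(pairs, "mode")
  missing_codes <- setdiff(unique(c(pairs$x, pairs$y)), names(profiles))
  if (length(missing_codes) > 0) {
    dz_error("diseasome_integrity_error",
             sprintf("pair references code(s) without a profile: %s",
                     paste(missing_codes, collapse = ", ")))
  }
  sizes <- lengths(profiles)
  n_x <- unname(sizes[pairs$x])
  n_y <- unname(sizes[pairs$y])
  s <- pairs$n_shared
  rec <- data.frame(
    x = c(pairs$x, pairs$y),
    y = c(pairs$y, pairs$x),
    mode = mode,
    n_x = c(n_x, n_y),
    n_y = c(n_y, n_x),
    shared = c(s, s),
    stringsAsFactors = FALSE)
  rec$tau <- rec$shared / rec$n_x
  rec <- rec[order(rec$x, rec$y), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

## five-number summary with type-7 (linear interpolation) quartiles
dist_summary <- function(values, group) {
  if (length(values) == 0) {
    return(data.frame(group = character(0), n = integer(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE))
  }
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  data.frame(group = group, n = length(values),
             min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             stringsAsFactors = FALSE)
}

#' Same-category inclusion distributions
#'
#' Summarizes the directed inclusion values of disease pairs whose two
#' codes fall in the same ICD-10-CM chapter: one five-number summary
#' (type-7 linear-interpolation quartiles) per chapter that has at least
#' one same-chapter record. Cross-chapter records contribute nothing.
#'
#' @param records data.frame from [all_directed_inclusions()].
#' @param chapters chapter table, default [icd10_chapters()].
#' @return data.frame with columns `group` (chapter range), `n`, `min`,
#'   `q1`, `median`, `q3`, `max`; attribute `quartile_type = 7`.
#' @export
same_category_summary <- function(records, chapters = icd10_chapters()) {
  codes <- unique(c(records$x, records$y))
  chap <- assign_chapter(codes, chapters)
  names(chap) <- codes
  cx <- unname(chap[records$x])
  cy <- unname(chap[records$y])
  same <- cx == cy
  if (!any(same)) {
    out <- dist_summary(numeric(0), character(0))[0, ]
    attr(out, "quartile_type") <- 7
    return(out)
  }
  groups <- split(records$tau[same], cx[same])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    dist_summary(groups[[g]], g)
  }))
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quartile_type") <- 7
  out
}

#' Inclusion directionality for a focal chapter
#'
#' Splits directed inclusion records by the role a focal chapter (for
#' example neoplasms, `"C00-D49"`) plays in each cross-chapter pair:
#' `as_X` collects records whose X code lies in the focal chapter and whose
#' Y code does not, `as_Y` the reverse. Records with both codes in the
#' focal chapter belong to [same_category_summary()] and are excluded.
#'
#' @param records data.frame from [all_directed_inclusions()].
#' @param focal chapter range label, e.g. `"C00-D49"`.
#' @param split_by_partner if `TRUE`, each role is summarized per partner
#'   chapter (the non-focal code's chapter) instead of overall.
#' @param chapters chapter table, default [icd10_chapters()].
#' @return list with elements `as_X` and `as_Y`; each holds `values`
#'   (the raw tau values) and `summary` (a five-number summary data.frame,
#'   one row overall or one per partner chapter).
#' @export
focal_directionality <- function(records, focal, split_by_partner = FALSE,
                                 chapters = icd10_chapters()) {
  chapters <- validate_chapters(chapters)
  if (!focal %in% chapters$range) {
    dz_error("diseasome_contract_error",
             sprintf("focal chapter '%s' not in the chapter table", focal))
  }
  codes <- unique(c(records$x, records$y))
  chap <- assign_chapter(codes, chapters)
  names(chap) <- codes
  cx <- unname(chap[records$x])
  cy <- unname(chap[records$y])

  role_out <- function(sel, partner_chap) {
    values <- records$tau[sel]
    partners <- partner_chap[sel]
    if (length(values) == 0) {
      smry <- dist_summary(numeric(0), character(0))[0, ]
    } else if (split_by_partner) {
      groups <- split(values, partners)
      smry <- do.call(rbind, lapply(names(groups), function(g) {
        dist_summary(groups[[g]], g)
      }))
      smry <- smry[order(smry$group), , drop = FALSE]
      rownames(smry) <- NULL
    } else {
      smry <- dist_summary(values, "overall")
    }
    list(values = values, partner_chapter = partners, summary = smry)
  }

  list(as_X = role_out(cx == focal & cy != focal, cy),
       as_Y = role_out(cy == focal & cx != focal, cx))
}
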