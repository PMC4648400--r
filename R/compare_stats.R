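#' Correlate ER profiles of two datasets
#'
#' Pearson correlation of per-transition ER scores between two transition
#' tables (e.g. two organisms), over the synonymous or nonsynonymous
#' subset (nonsynonymous = Similar, Somewhat different and Very different
#' categories). Transitions missing from either table are dropped and
#' counted.
#'
#' @param table_a,table_b `transition_table`s (or data.frames with
#'   `transition`, `ER`, `category` columns).
#' @param subset `"nonsynonymous"` or `"synonymous"`.
#' @return list with `rho`, `p_value`, `n_pairs`, `n_dropped`. Fewer than
#'   3 pairs yield NA.
#' @export
er_correlation <- function(table_a, table_b,
                           subset = c("nonsynonymous", "synonymous")) {
  subset <- match.arg(subset)
  want <- if (subset == "nonsynonymous") nonsynonymous_categories()
          else "Synonymous"
  a <- table_a[table_a$category %in% want, c("transition", "ER")]
  b <- table_b[table_b$category %in% want, c("transition", "ER")]
  common <- intersect(a$transition, b$transition)
  n_dropped <- length(setdiff(union(a$transition, b$transition), common))
  if (length(common) < 3L) {
    return(list(rho = NA_real_, p_value = NA_real_,
                n_pairs = length(common), n_dropped = n_dropped))
  }
  x <- a$ER[match(common, a$transition)]
  y <- b$ER[match(common, b$transition)]
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(common), n_dropped = n_dropped)
}

#' Rank-sum comparison of two ER groups
#'
#' Two-sided Wilcoxon-Mann-Whitney test (midrank ties) between two sets of
#' ER values, reporting the W statistic for the first sample. With
#' `absolute = TRUE` the comparison is on |ER| magnitudes, as used when
#' contrasting the strength of enrichment/depletion between organisms.
#' The exact null distribution is used for small untied samples
#' (both sizes <= 20), the normal approximation with tie correction
#' otherwise.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param absolute compare absolute values.
#' @return list with `W`, `p_value`, `n_a`, `n_b`.
#' @export
er_group_comparison <- function(values_a, values_b, absolute = FALSE) {
  stopifnot(length(values_a) > 0L, length(values_b) > 0L)
  if (absolute) {
    values_a <- abs(values_a)
    values_b <- abs(values_b)
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- !ties && length(values_a) <= 20L && length(values_b) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}
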