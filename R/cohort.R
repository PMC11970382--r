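## Cohort composition dynamics: per-sample cell-type fractions, paired
## pre/post tests, group comparisons, clinical response-rate summaries,
## and significance stars.

#' Per-sample cell-type composition fractions
#'
#' Converts a per-cell annotation table into per-sample fractions;
#' absent types get 0 so every sample has the full type vector, and
#' fractions sum to 1 per sample.
#'
#' @param cells data.frame with columns `sample_id`, `cell_type`
#'   (see [schema_cell_annotation]).
#' @param cell_types Optional fixed type universe (default: all types seen).
#' @return data.frame: `sample_id` plus one numeric fraction column per
#'   cell type.
#' @examples
#' composition_fractions(data.frame(sample_id = "s1",
#'                                  cell_type = c("T", "T", "B", "B")))
#' @export
composition_fractions <- function(cells, cell_types = NULL) {
  stopifnot(all(c("sample_id", "cell_type") %in% names(cells)))
  if (nrow(cells) == 0L) stop("empty cell table")
  if (is.null(cell_types)) cell_types <- sort(unique(cells$cell_type))
  tab <- table(factor(cells$sample_id),
               factor(cells$cell_type, levels = cell_types))
  if (any(rowSums(tab) == 0L)) stop("sample with no cells")
  frac <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  out <- data.frame(sample_id = rownames(frac), frac, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Paired pre/post change test (two-sided paired t-test)
#'
#' Student's paired t-test on per-patient differences `post - pre`
#' (algebraically, a one-sample t-test of the differences against 0).
#' Zero-variance differences give `p = NaN` with a warning rather than an
#' error, so degenerate simulated cohorts are reported, not dropped.
#'
#' @param pre,post Numeric fraction vectors aligned by patient (same
#'   length, >= 2 complete pairs).
#' @return List: `statistic` (t), `df`, `p_value` (two-sided),
#'   `mean_change` (mean of `post - pre`), `n`.
#' @examples
#' paired_change_test(c(0, 0, 0), c(1, 2, 3))  # t = 3.464, p ~ 0.074
#' @export
paired_change_test <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]
  post <- post[keep]
  n <- length(pre)
  if (n < 2L) stop("need >= 2 complete pairs")
  d <- post - pre
  if (sd(d) == 0) {
    warning("zero-variance differences: p is NaN")
    return(list(statistic = NaN, df = n - 1L, p_value = NaN,
                mean_change = mean(d), n = n))
  }
  ht <- t.test(d, mu = 0)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_change = mean(d), n = n)
}

#' Compare fraction distributions between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test between two groups of
#' per-sample fractions; the same implementation (and exactness policy) as
#' [compare_in_out()]. For paired pre/post designs the signed-rank variant
#' is available via `paired = TRUE`.
#'
#' @param group_a,group_b Numeric fraction vectors.
#' @param paired Use the Wilcoxon signed-rank test on aligned pairs.
#' @return List: `statistic`, `p_value`, `method`.
#' @export
group_fraction_test <- function(group_a, group_b, paired = FALSE) {
  if (paired) {
    stopifnot(length(group_a) == length(group_b))
    ht <- suppressWarnings(wilcox.test(group_a, group_b, paired = TRUE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "signed_rank"))
  }
  wilcox_rank_sum(group_a, group_b)
}

#' Clinical response rates as printed percentages
#'
#' Converts per-category response counts into percentages of the arm size,
#' truncated (rounded down) to one decimal — the convention that
#' reproduces printed trial percentages such as 3/34 = 8.8% and
#' 16/34 = 47.0%.
#'
#' @param counts Non-negative integer count(s), optionally named by
#'   category (e.g. `c(PR = 3, SD = 25, PD = 4, NE = 2)`).
#' @param n Arm size, > 0; `counts` must not exceed `n`.
#' @return Numeric percentage(s) with one decimal, named like `counts`.
#' @examples
#' response_rates(c(PR = 3), 34)   # 8.8
#' response_rates(c(PR = 16), 34)  # 47.0
#' @export
response_rates <- function(counts, n) {
  stopifnot(length(n) == 1L)
  if (!is.finite(n) || n <= 0) stop("arm size n must be > 0")
  if (any(counts < 0) || any(counts > n)) {
    stop("counts must be between 0 and n")
  }
  floor(1000 * counts / n + 1e-9) / 10
}

#' Significance stars for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05
#' (strict inequalities), `"ns"` otherwise, `"NE"` for NaN/NA.
#'
#' @param p Numeric p-value(s) in `[0, 1]`, NA/NaN allowed.
#' @return Character vector of annotations.
#' @examples
#' star_annotation(c(0.04, 0.005, 0.0005, 0.05, NaN))
#' @export
star_annotation <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must be in [0, 1]")
  out <- ifelse(is.na(p), "NE",
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns"))))
  out
}

#' Per-type paired composition change table for a cohort
#'
#' Convenience wrapper over [paired_change_test()]: for each cell type
#' (and optionally one arm), pairs each patient's baseline and post rows
#' and reports the mean change, t-statistic, p-value, and stars.
#'
#' @param cohort Cohort table as produced by [simulate_cohort()] (columns
#'   `patient`, `arm`, `timepoint`, `response`, then fraction columns).
#' @param arm Optional arm filter.
#' @param cell_types Types to test (default: all fraction columns).
#' @return data.frame: `cell_type`, `n_pairs`, `mean_change`, `statistic`,
#'   `p_value`, `stars`.
#' @export
composition_change_table <- function(cohort, arm = NULL, cell_types = NULL) {
  need <- c("patient", "arm", "timepoint")
  stopifnot(all(need %in% names(cohort)))
  if (!is.null(arm)) cohort <- cohort[cohort$arm %in% arm, , drop = FALSE]
  if (is.null(cell_types)) {
    cell_types <- setdiff(names(cohort),
                          c("patient", "arm", "timepoint", "response"))
  }
  pre <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  post <- cohort[cohort$timepoint == "post", , drop = FALSE]
  common <- intersect(pre$patient, post$patient)
  if (length(common) < 2L) stop("need >= 2 complete pairs")
  pre <- pre[match(common, pre$patient), , drop = FALSE]
  post <- post[match(common, post$patient), , drop = FALSE]
  rows <- lapply(cell_types, function(tp) {
    ht <- suppressWarnings(paired_change_test(pre[[tp]], post[[tp]]))
    data.frame(cell_type = tp, n_pairs = ht$n,
               mean_change = ht$mean_change, statistic = ht$statistic,
               p_value = ht$p_value, stars = star_annotation(ht$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
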