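## Region-of-interest analysis: ROIs by above-average deconvolved abundance,
## depth-normalized expression, control-gene-matched signature scores,
## ligand-receptor co-expression, and in/out-ROI rank-sum comparison.

#' Depth-normalize a count matrix
#'
#' Scales each spot's counts to the median library size across spots, then
#' applies `log(1 + x)`. Spots with zero library size get `NaN` profiles
#' and are flagged with a warning and in `attr(x, "zero_library")`.
#'
#' @param counts genes x spots matrix (as from [read_counts_mtx()] or
#'   `simulate_spatial_map()$counts`), or spots x genes if
#'   `spots_as_rows = TRUE`.
#' @param spots_as_rows Set TRUE if `counts` is already spots x genes.
#' @return spots x genes dense numeric matrix of log-normalized
#'   expression, with attributes `normalization` (method record) and
#'   `zero_library` (spot ids with zero counts).
#' @export
normalize_expression <- function(counts, spots_as_rows = FALSE) {
  m <- as.matrix(counts)
  if (!spots_as_rows) m <- t(m)      # -> spots x genes
  lib <- rowSums(m)
  zero <- lib == 0
  if (any(zero)) {
    warning(sum(zero), " spot(s) with zero library size; scores will be NaN")
  }
  target <- median(lib[!zero])
  norm <- log1p(m / lib * target)    # rows with lib 0 become NaN
  attr(norm, "normalization") <- list(method = "median_depth_log1p",
                                      target_depth = target)
  attr(norm, "zero_library") <- rownames(m)[zero]
  norm
}

#' Define a region of interest by above-average abundance
#'
#' The ROI of a cell subset is the set of spots where its estimated
#' abundance strictly exceeds the mean over analyzed spots.
#'
#' @param abundance Finite numeric vector (one value per analyzed spot).
#' @param spot_id Optional spot identifiers for the mask names.
#' @return Object of class `"roi_mask"`: logical vector with attributes
#'   `threshold` (the mean) and `n_in`. Constant input yields an empty
#'   mask with a warning.
#' @examples
#' define_roi(c(1, 2, 3, 6))  # mean 3 -> only the last spot
#' @export
define_roi <- function(abundance, spot_id = NULL) {
  if (any(!is.finite(abundance))) stop("abundance must be finite")
  thr <- mean(abundance)
  mask <- abundance > thr
  if (!any(mask)) {
    warning("empty ROI: no spot exceeds the mean abundance")
  }
  if (!is.null(spot_id)) names(mask) <- spot_id
  structure(mask, threshold = thr, n_in = sum(mask), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %d of %d spots above mean abundance (threshold %.4g)\n",
              attr(x, "n_in"), length(x), attr(x, "threshold")))
  invisible(x)
}

#' Proportion of spots with higher-than-average abundance
#'
#' The per-type spot proportion: `|{a > mean(a)}| / n`. Consistent with
#' [define_roi()] — the numerator is exactly the ROI size.
#'
#' @param abundance Finite numeric vector.
#' @return Proportion in `[0, 1]`.
#' @examples
#' proportion_above_average(c(1, 2, 3, 6))  # 0.25
#' @export
proportion_above_average <- function(abundance) {
  if (any(!is.finite(abundance))) stop("abundance must be finite")
  mean(abundance > mean(abundance))
}

#' Control-gene-matched signature score
#'
#' Scores a gene set per spot against expression-matched control genes:
#' all genes are ranked by mean normalized expression and split into
#' `n_bins_ctrl` equal-size bins; for each signature gene,
#' `n_ctrl_per_gene` control genes are sampled from its bin (signature
#' genes excluded; with replacement when the bin is small), and the score
#' per spot is `mean(signature genes) - mean(control genes)` over the
#' pooled control multiset. Deterministic given `seed`.
#'
#' @param expr spots x genes normalized expression matrix
#'   (from [normalize_expression()]).
#' @param gene_set Character vector of signature genes (subset of
#'   `colnames(expr)`); genes with zero total expression are dropped with
#'   a warning.
#' @param n_bins_ctrl Number of expression bins (default 25).
#' @param n_ctrl_per_gene Control genes sampled per signature gene
#'   (default 50).
#' @param seed Integer seed for the control draw.
#' @return Numeric per-spot score vector (class `"score_vector"`) with
#'   attributes `kind = "signature"`, `genes`, `controls`.
#' @export
signature_score <- function(expr, gene_set, n_bins_ctrl = 25L,
                            n_ctrl_per_gene = 50L, seed = 1L) {
  stopifnot(is.matrix(expr), n_bins_ctrl >= 1L, n_ctrl_per_gene >= 1L)
  genes <- colnames(expr)
  missing_genes <- setdiff(gene_set, genes)
  if (length(missing_genes)) {
    stop("gene(s) not in expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  totals <- colSums(expr)
  drop <- intersect(gene_set, genes[is.finite(totals) & totals == 0])
  if (length(drop)) {
    warning("dropping zero-expression signature gene(s): ",
            paste(drop, collapse = ", "))
    gene_set <- setdiff(gene_set, drop)
  }
  if (!length(gene_set)) stop("empty gene set after filtering")
  ## rank genes by mean expression into equal-size bins
  means <- colMeans(expr)
  rk <- rank(means, ties.method = "first")
  bin <- ceiling(rk / (length(genes) / n_bins_ctrl))
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      cand <- genes[bin == bin[match(g, genes)]]
      cand <- setdiff(cand, gene_set)
      if (!length(cand)) {
        cand <- setdiff(genes, gene_set)   # degenerate bin: fall back
      }
      cand[sample.int(length(cand), n_ctrl_per_gene,
                      replace = length(cand) < n_ctrl_per_gene)]
    }))
  })
  score <- rowMeans(expr[, gene_set, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  structure(score, kind = "signature", genes = gene_set,
            controls = ctrl, class = "score_vector")
}

#' Ligand-receptor co-expression score
#'
#' Per-spot co-expression of a ligand-receptor pair: the arithmetic mean
#' of the two genes' (normalized) expression values.
#'
#' @param expr spots x genes normalized expression matrix.
#' @param ligand,receptor Gene names (must be columns of `expr`).
#' @return Numeric per-spot score vector (class `"score_vector"`,
#'   `kind = "lr_coexpression"`).
#' @export
lr_coexpression <- function(expr, ligand, receptor) {
  for (g in c(ligand, receptor)) {
    if (!g %in% colnames(expr)) stop("gene not in expression matrix: ", g)
  }
  score <- (expr[, ligand] + expr[, receptor]) / 2
  structure(score, kind = "lr_coexpression",
            genes = c(ligand = ligand, receptor = receptor),
            class = "score_vector")
}

## Single Wilcoxon rank-sum (Mann-Whitney) implementation shared by the ROI
## and cohort modules: exact enumeration for small untied samples, else the
## tie-corrected normal approximation with continuity correction.
wilcox_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, conf.int = FALSE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Compare scores inside vs outside an ROI (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test of the score
#' distribution inside the ROI against outside. Exact enumeration is used
#' when the smaller group has <= 8 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param scores Per-spot numeric scores (e.g. from [signature_score()] or
#'   [lr_coexpression()]).
#' @param mask Logical ROI mask of the same length ([define_roi()]).
#' @return List: `statistic` (rank-sum U of the in-group), `p_value`
#'   (two-sided), `median_in`, `median_out`, `n_in`, `n_out`, `method`.
#' @examples
#' compare_in_out(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
#' @export
compare_in_out <- function(scores, mask) {
  stopifnot(length(scores) == length(mask))
  mask <- as.logical(mask)
  a <- scores[mask]
  b <- scores[!mask]
  if (!length(a) || !length(b)) {
    stop("both ROI groups must be non-empty")
  }
  ht <- wilcox_rank_sum(a, b)
  c(ht[c("statistic", "p_value")],
    list(median_in = median(a), median_out = median(b),
         n_in = length(a), n_out = length(b), method = ht$method))
}
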