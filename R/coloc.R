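## Spatial co-localization of deconvolved cell types: per-type density
## histograms on a shared grid, pairwise KL divergence (NaN on empty
## histograms), a subsample-and-shuffle permutation null, and empirical
## p-values.

#' Extract a cell type's spot membership from its abundance column
#'
#' `"above_average"` returns the indices of spots whose abundance is
#' strictly greater than the mean over the analyzed spots (the same rule
#' that defines ROIs and the reported per-type spot proportions);
#' `"weighted"` returns the abundance vector itself, to be used as
#' histogram weights.
#'
#' @param abundance Numeric vector of finite, non-negative abundances.
#' @param mode `"above_average"` or `"weighted"`.
#' @return Integer indices (above_average; possibly empty) or the numeric
#'   weight vector (weighted).
#' @examples
#' assign_spots(c(1, 2, 3, 6))   # mean 3 -> spot 4 only
#' @export
assign_spots <- function(abundance, mode = c("above_average", "weighted")) {
  mode <- match.arg(mode)
  if (any(!is.finite(abundance))) stop("abundance must be finite")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (mode == "weighted") return(abundance)
  which(abundance > mean(abundance))
}

## Shared bounding box of the analyzed spots: c(xmin, xmax, ymin, ymax).
spot_bbox <- function(x, y) c(range(x), range(y))

bin_index <- function(v, lo, hi, n_bins) {
  ## half-open bins [lo_i, hi_i), top edge right-inclusive
  i <- floor((v - lo) / (hi - lo) * n_bins) + 1
  pmin(pmax(as.integer(i), 1L), n_bins)
}

#' Spatial density histogram of a spot membership
#'
#' Bins member spots on a grid over the bounding box of *all* analyzed
#' spots (shared across cell types, so histograms are comparable pair to
#' pair) and normalizes to total mass 1. With `hist_kind = "grid2d"` the
#' grid is `n_bins x n_bins`; with `"per_axis"` the mass is the
#' concatenation of two 1-D `n_bins` histograms (x then y), half the mass
#' each. Bins are half-open with a right-inclusive top edge. An empty
#' membership yields an all-zero histogram with `empty = TRUE`.
#'
#' @param spots Spot table (`spot_id`, `x`, `y`, ...).
#' @param membership Integer/logical index of member spots, or a numeric
#'   weight vector of length `nrow(spots)` (from [assign_spots()] in
#'   weighted mode).
#' @param config A [run_config()].
#' @param bbox Optional bounding box `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the bounding box of `spots`.
#' @return An object of class `"density_histogram"`: list with `mass`
#'   (numeric vector of bin masses), `n_bins`, `hist_kind`, `bbox`,
#'   `n_members`, `empty`.
#' @export
density_histogram <- function(spots, membership, config = run_config(),
                              bbox = NULL) {
  x <- spots$x
  y <- spots$y
  if (is.null(bbox)) bbox <- spot_bbox(x, y)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate geometry: bounding box has zero width or height")
  }
  nb <- config$n_bins
  if (is.logical(membership)) {
    stopifnot(length(membership) == nrow(spots))
    membership <- which(membership)
  }
  ## doubles of length n are weight vectors (weighted mode); integers index
  weighted <- is.double(membership)
  if (weighted) {
    w <- membership
    stopifnot(length(w) == nrow(spots))
    keep <- w > 0
    xs <- x[keep]; ys <- y[keep]; w <- w[keep]
  } else {
    xs <- x[membership]; ys <- y[membership]
    w <- rep(1, length(xs))
  }
  n_cells <- if (config$hist_kind == "grid2d") nb * nb else 2L * nb
  mass <- numeric(n_cells)
  empty <- length(xs) == 0L
  if (!empty) {
    ix <- bin_index(xs, bbox[1], bbox[2], nb)
    iy <- bin_index(ys, bbox[3], bbox[4], nb)
    if (config$hist_kind == "grid2d") {
      cell <- (iy - 1L) * nb + ix
      mass <- bin_sum(cell, w, n_cells)
    } else {
      mass <- c(bin_sum(ix, w, nb), bin_sum(iy, w, nb)) / 2
    }
    mass <- mass / sum(mass)
  }
  structure(
    list(mass = mass, n_bins = nb, hist_kind = config$hist_kind,
         bbox = bbox, n_members = length(xs), empty = empty),
    class = "density_histogram"
  )
}

bin_sum <- function(idx, w, n_cells) {
  if (all(w == 1)) return(tabulate(idx, nbins = n_cells))
  out <- numeric(n_cells)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Kullback-Leibler divergence between two density histograms
#'
#' Computes `D(P || Q) = sum p'_i log(p'_i / q'_i)` in nats, where `p'`,
#' `q'` are the histograms with `epsilon` added to every bin and
#' renormalized. Both histograms must share the same grid and be
#' non-empty; empty histograms must be routed to the NaN path by the
#' caller (as [coloc_matrix()] does).
#'
#' @param p,q `density_histogram` objects on the same grid, or bare
#'   non-negative numeric vectors of equal length.
#' @param epsilon Pseudo-count (default from [run_config()]).
#' @return Non-negative finite scalar (nats); exactly 0 when `p` and `q`
#'   are identical.
#' @examples
#' kl_divergence(c(0.75, 0.25), c(0.25, 0.75))  # ~ 0.5 * log(3)
#' @export
kl_divergence <- function(p, q, epsilon = 1e-10) {
  if (inherits(p, "density_histogram") || inherits(q, "density_histogram")) {
    stopifnot(inherits(p, "density_histogram"),
              inherits(q, "density_histogram"))
    if (p$n_bins != q$n_bins || p$hist_kind != q$hist_kind ||
        !isTRUE(all.equal(p$bbox, q$bbox))) {
      stop("histograms are on different bin grids")
    }
    if (p$empty || q$empty) {
      stop("empty histogram: route empty pairs to NaN instead")
    }
    p <- p$mass
    q <- q$mass
  }
  stopifnot(length(p) == length(q), epsilon > 0)
  if (any(p < 0) || any(q < 0)) stop("histogram masses must be non-negative")
  ps <- (p / sum(p) + epsilon)
  qs <- (q / sum(q) + epsilon)
  ps <- ps / sum(ps)
  qs <- qs / sum(qs)
  sum(ps * (log(ps) - log(qs)))
}

#' Jensen-Shannon divergence (symmetric summary)
#'
#' `JSD(P, Q) = D(P || M)/2 + D(Q || M)/2` with `M = (P + Q)/2`, using the
#' same epsilon smoothing as [kl_divergence()]. Offered as an optional
#' symmetric alternative to the directed KL matrix.
#'
#' @inheritParams kl_divergence
#' @return Scalar in `[0, log 2]` nats.
#' @export
js_divergence <- function(p, q, epsilon = 1e-10) {
  if (inherits(p, "density_histogram")) p <- p$mass
  if (inherits(q, "density_histogram")) q <- q$mass
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  (kl_divergence(p, m, epsilon) + kl_divergence(q, m, epsilon)) / 2
}

## Core: memberships -> histogram matrix -> full pairwise KL matrix.
## x, y: coordinates of the analyzed spots; A: spots x types abundance.
## Returns list(kl = T x T matrix, empty = logical per type).
kl_matrix_core <- function(x, y, A, config) {
  nb <- config$n_bins
  n_cells <- if (config$hist_kind == "grid2d") nb * nb else 2L * nb
  bbox <- spot_bbox(x, y)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate geometry: bounding box has zero width or height")
  }
  ix <- bin_index(x, bbox[1], bbox[2], nb)
  iy <- bin_index(y, bbox[3], bbox[4], nb)
  K <- ncol(A)
  H <- matrix(0, n_cells, K)
  empty <- logical(K)
  mu <- colMeans(A)
  for (k in seq_len(K)) {
    if (config$membership_mode == "above_average") {
      mem <- A[, k] > mu[k]
      w <- NULL
      n_mem <- sum(mem)
    } else {
      w <- A[, k]
      mem <- w > 0
      n_mem <- sum(mem)
    }
    if (n_mem == 0L) {
      empty[k] <- TRUE
      next
    }
    if (config$hist_kind == "grid2d") {
      cell <- (iy[mem] - 1L) * nb + ix[mem]
      h <- if (is.null(w)) tabulate(cell, nbins = n_cells) else
        bin_sum(cell, w[mem], n_cells)
    } else {
      if (is.null(w)) {
        h <- c(tabulate(ix[mem], nbins = nb), tabulate(iy[mem], nbins = nb)) / 2
      } else {
        h <- c(bin_sum(ix[mem], w[mem], nb), bin_sum(iy[mem], w[mem], nb)) / 2
      }
    }
    H[, k] <- h / sum(h)
  }
  eps <- config$epsilon
  P <- H + eps
  P <- sweep(P, 2L, colSums(P), "/")
  L <- log(P)
  cross <- t(P) %*% L              # cross[i, j] = sum_b p_i log p_j
  kl <- matrix(diag(cross), K, K) - cross
  kl[kl < 0] <- 0                  # guard against -0 / rounding
  kl[empty, ] <- NaN
  kl[, empty] <- NaN
  dimnames(kl) <- list(colnames(A), colnames(A))
  list(kl = kl, empty = empty)
}

#' Observed pairwise KL divergence matrix
#'
#' Computes the directed KL divergence between the spatial density
#' histograms of every ordered cell-type pair on the analyzed spots.
#' Types whose membership is empty (no spot strictly above the mean
#' abundance) produce `NaN` in their entire row and column; the diagonal
#' is exactly 0 where defined.
#'
#' @param spots Spot table (`spot_id`, `x`, `y`, optionally `in_tissue`).
#' @param abundance Spots x cell-types numeric matrix (rownames matching
#'   `spot_id` if present, otherwise row order is used), or a data.frame
#'   with a `spot_id` column.
#' @param config A [run_config()].
#' @param include_out_of_tissue Keep spots flagged `in_tissue = FALSE`
#'   (default drops them).
#' @return Cell types x cell types numeric matrix (NaN allowed).
#' @export
coloc_matrix <- function(spots, abundance, config = run_config(),
                         include_out_of_tissue = FALSE) {
  al <- align_map(spots, abundance, include_out_of_tissue)
  kl_matrix_core(al$x, al$y, al$A, config)$kl
}

## Align spot table and abundance matrix; returns coordinates + matrix for
## the analyzed (in-tissue, unless included) spots.
align_map <- function(spots, abundance, include_out_of_tissue = FALSE) {
  validate_spot_table(spots)
  if (is.data.frame(abundance)) {
    if ("spot_id" %in% names(abundance)) {
      rn <- abundance$spot_id
      abundance <- as.matrix(abundance[setdiff(names(abundance), "spot_id")])
      rownames(abundance) <- rn
    } else {
      abundance <- as.matrix(abundance)
    }
  }
  if (ncol(abundance) < 2L) stop("need at least 2 cell types")
  if (!is.null(rownames(abundance))) {
    miss <- setdiff(spots$spot_id, rownames(abundance))
    if (length(miss)) {
      stop("abundance matrix is missing spot(s): ",
           paste(head(miss, 3L), collapse = ", "))
    }
    abundance <- abundance[spots$spot_id, , drop = FALSE]
  } else if (nrow(abundance) != nrow(spots)) {
    stop("abundance rows (", nrow(abundance), ") != spots (", nrow(spots), ")")
  }
  keep <- if (include_out_of_tissue || is.null(spots$in_tissue)) {
    rep(TRUE, nrow(spots))
  } else {
    spots$in_tissue
  }
  if (sum(keep) < 2L) stop("fewer than 2 analyzed spots")
  if (any(!is.finite(abundance[keep, ]))) stop("abundance must be finite")
  if (any(abundance[keep, ] < 0)) stop("abundance must be non-negative")
  list(x = spots$x[keep], y = spots$y[keep],
       A = abundance[keep, , drop = FALSE],
       spot_id = spots$spot_id[keep])
}

#' Permutation null for the KL co-localization test
#'
#' For each permutation: draw `floor(subsample_frac * n)` analyzed spots
#' without replacement, permute the `(x, y)` coordinate tuples jointly
#' among the sampled spots (abundance rows stay fixed), and recompute
#' memberships, histograms, and the full KL matrix on the sampled set.
#' Per-permutation RNG substreams are derived deterministically from the
#' master seed, so the null is a pure function of (inputs, config).
#'
#' @inheritParams coloc_matrix
#' @return 3-d array `n_perm x types x types` of null KL values.
#' @export
permutation_null <- function(spots, abundance, config = run_config(),
                             include_out_of_tissue = FALSE) {
  al <- align_map(spots, abundance, include_out_of_tissue)
  n <- length(al$x)
  m <- floor(config$subsample_frac * n)
  if (m < 2L) stop("subsample smaller than 2 spots")
  K <- ncol(al$A)
  perm_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, config$n_perm))
  null <- array(NA_real_, dim = c(config$n_perm, K, K),
                dimnames = list(NULL, colnames(al$A), colnames(al$A)))
  for (b in seq_len(config$n_perm)) {
    null[b, , ] <- with_seed(perm_seeds[b], {
      idx <- sample.int(n, m)
      shuf <- sample.int(m)
      kl_matrix_core(al$x[idx][shuf], al$y[idx][shuf],
                     al$A[idx, , drop = FALSE], config)$kl
    })
  }
  null
}

#' Empirical p-value from a permutation null
#'
#' With `tail = "as_written"`, `p = (#\{null > observed\} + 1) / (#null + 1)`
#' — the fraction of permutations whose KL exceeds the observed value
#' (plus-one corrected). Under this orientation a strongly co-localized
#' pair (small KL) gets p near 1. With `tail = "co_localization"`,
#' `p = (#\{null < observed\} + 1) / (#null + 1)`, so small KL is
#' significant. A `NaN` observed value yields `NaN`.
#'
#' @param observed Observed KL (scalar).
#' @param null Numeric vector of null KL values (NaN entries are dropped).
#' @param tail `"as_written"` or `"co_localization"`.
#' @return p-value in `[1/(n+1), 1]`, or NaN.
#' @examples
#' empirical_pvalue(0.25, c(0.1, 0.2, 0.3, 0.4))  # (2+1)/(4+1)
#' @export
empirical_pvalue <- function(observed, null,
                             tail = c("as_written", "co_localization")) {
  tail <- match.arg(tail)
  if (is.na(observed)) return(NaN)
  null <- null[!is.na(null)]
  if (!length(null)) return(NaN)
  k <- if (tail == "as_written") sum(null > observed) else sum(null < observed)
  (k + 1) / (length(null) + 1)
}

#' Co-localization test of deconvolved cell-type maps
#'
#' Runs the full spatial co-localization analysis: the observed pairwise
#' KL matrix on all analyzed spots, the subsample-and-shuffle permutation
#' null, and empirical p-values for both tails. The reference statistic
#' compared against the null follows `config$observed_scope`: by default
#' it is recomputed on one seeded, unshuffled subsample of the same size
#' as the null subsamples, so the comparison is calibrated (see
#' [run_config()]).
#'
#' @inheritParams coloc_matrix
#' @return Object of class `"coloc_result"`: list with `types`, `kl`
#'   (observed matrix, all analyzed spots), `kl_ref` (reference statistic
#'   used for p-values), `null_kl` (n_perm x T x T array), `pvals` (matrix
#'   for `config$tail`), `pvals_as_written`, `pvals_co_localization`,
#'   `n_spots`, `config`.
#' @examples
#' sim <- simulate_spatial_map(n_spots = 120, cell_types = c("A", "B", "C"),
#'                             seed = 1)
#' res <- coloc_test(sim$spots, sim$abundance,
#'                   run_config(n_perm = 50, seed = 1))
#' res$pvals
#' @export
coloc_test <- function(spots, abundance, config = run_config(),
                       include_out_of_tissue = FALSE) {
  al <- align_map(spots, abundance, include_out_of_tissue)
  n <- length(al$x)
  kl_obs <- kl_matrix_core(al$x, al$y, al$A, config)$kl
  null <- permutation_null(spots, abundance, config, include_out_of_tissue)
  kl_ref <- kl_obs
  if (config$observed_scope == "subsample_matched") {
    m <- floor(config$subsample_frac * n)
    ## reference subsample drawn from a dedicated substream of the master
    ## seed (offset so it differs from every permutation substream)
    ref_seed <- with_seed(config$seed + 1L,
                          sample.int(.Machine$integer.max - 1L, 1L))
    kl_ref <- with_seed(ref_seed, {
      idx <- sample.int(n, m)
      kl_matrix_core(al$x[idx], al$y[idx], al$A[idx, , drop = FALSE],
                     config)$kl
    })
  }
  K <- ncol(al$A)
  p_aw <- p_co <- matrix(NaN, K, K, dimnames = dimnames(kl_obs))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      obs <- kl_ref[i, j]
      if (is.na(kl_obs[i, j]) || is.na(obs)) next
      p_aw[i, j] <- empirical_pvalue(obs, null[, i, j], "as_written")
      p_co[i, j] <- empirical_pvalue(obs, null[, i, j], "co_localization")
    }
  }
  structure(
    list(
      types = colnames(al$A), kl = kl_obs, kl_ref = kl_ref, null_kl = null,
      pvals = if (config$tail == "as_written") p_aw else p_co,
      pvals_as_written = p_aw, pvals_co_localization = p_co,
      n_spots = n, config = config
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "Co-localization test: %d cell types, %d spots, %d permutations\n",
    length(x$types), x$n_spots, x$config$n_perm))
  cat(sprintf("  tail = %s, observed scope = %s\n",
              x$config$tail, x$config$observed_scope))
  n_nan <- sum(is.na(x$kl[upper.tri(x$kl)]))
  cat(sprintf("  KL matrix: %d NaN pair(s) above diagonal\n", n_nan))
  invisible(x)
}

#' @export
summary.coloc_result <- function(object, ...) {
  ut <- upper.tri(object$kl)
  df <- data.frame(
    type_a = rep(object$types, each = length(object$types))[ut],
    type_b = rep(object$types, times = length(object$types))[ut],
    kl_ab = object$kl[ut],
    p_as_written = object$pvals_as_written[ut],
    p_co_localization = object$pvals_co_localization[ut],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$kl_ab), ]
  rownames(df) <- NULL
  df
}

#' Plot a co-localization result
#'
#' Draws the KL divergence heatmap and, optionally, the null density for
#' one pair with the observed value marked.
#'
#' @param x A `coloc_result`.
#' @param pair Optional `c(type_a, type_b)` to show a null density panel.
#' @param ... Ignored.
#' @return `x` invisibly.
#' @export
plot.coloc_result <- function(x, pair = NULL, ...) {
  K <- length(x$types)
  if (!is.null(pair)) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  kl <- x$kl
  graphics::image(seq_len(K), seq_len(K), t(kl[K:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "KL divergence", col = grDevices::hcl.colors(64))
  graphics::axis(1, at = seq_len(K), labels = x$types, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(K), labels = rev(x$types), las = 2,
                 cex.axis = 0.7)
  if (!is.null(pair)) {
    i <- match(pair[1], x$types)
    j <- match(pair[2], x$types)
    if (is.na(i) || is.na(j)) stop("unknown pair type(s)")
    nulls <- x$null_kl[, i, j]
    nulls <- nulls[!is.na(nulls)]
    graphics::plot(stats::density(nulls), main = paste(pair, collapse = " vs "),
                   xlab = "KL (nats)")
    graphics::abline(v = x$kl_ref[i, j], col = "red", lwd = 2)
  }
  invisible(x)
}
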