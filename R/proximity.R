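## mIHC point-pattern proximity: nearest distances from phenotype-gated
## cells to niche objects, radial count profiles, and group comparisons.

#' Construct a point pattern from a coordinate table
#'
#' @param points data.frame with columns `cell_id`, `phenotype`, `x_um`,
#'   `y_um` (see [schema_point_pattern]); an `is_niche` logical column is
#'   honoured if present.
#' @param niche_phenotypes Phenotype label(s) marking niche objects; used
#'   to set `is_niche` when absent.
#' @return The data.frame with class `"point_pattern"` and a validated
#'   `is_niche` column.
#' @export
point_pattern <- function(points, niche_phenotypes = NULL) {
  need <- names(schema_point_pattern)
  miss <- setdiff(need, names(points))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(points$x_um)) || any(!is.finite(points$y_um))) {
    stop("point coordinates must be finite")
  }
  if (any(!nzchar(points$phenotype))) stop("phenotype labels must be non-empty")
  if (is.null(points$is_niche)) {
    points$is_niche <- points$phenotype %in% (niche_phenotypes %||% character())
  }
  class(points) <- c("point_pattern", "data.frame")
  points
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_xy <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    return(unname(p))
  }
  if (is.data.frame(p)) {
    if (all(c("x_um", "y_um") %in% names(p))) {
      return(cbind(p$x_um, p$y_um))
    }
    if (all(c("x", "y") %in% names(p))) return(cbind(p$x, p$y))
  }
  stop("expected a 2-column matrix or a data.frame with x/y coordinates")
}

#' Nearest distance from each target to a set of niche objects
#'
#' Euclidean centroid-to-centroid distance from every target point to its
#' nearest object point.
#'
#' @param targets,objects Point sets: data.frames with `x_um`/`y_um` (or
#'   `x`/`y`) columns, or 2-column matrices. `objects` must be non-empty.
#' @return Numeric vector of per-target distances (micrometres), named by
#'   `cell_id` when available.
#' @examples
#' nearest_distance(cbind(0, 0), cbind(3, 4))  # 5
#' @export
nearest_distance <- function(targets, objects) {
  tm <- as_xy(targets)
  om <- as_xy(objects)
  if (nrow(om) == 0L) stop("objects must be non-empty")
  if (nrow(tm) == 0L) return(numeric(0))
  d2 <- outer(tm[, 1], om[, 1], "-")^2 + outer(tm[, 2], om[, 2], "-")^2
  d <- sqrt(apply(d2, 1L, min))
  if (is.data.frame(targets) && "cell_id" %in% names(targets)) {
    names(d) <- targets$cell_id
  }
  d
}

#' Radial count profile of targets around niche objects
#'
#' Assigns each target to the annulus containing its nearest-object
#' distance (half-open `[lo, hi)` bins) and reports per-annulus counts and
#' area-normalized densities (count divided by the annulus area summed
#' over objects; overlap between objects is not corrected). Targets at or
#' beyond the last edge are collected in an overflow bucket, so counts
#' always sum to the number of targets.
#'
#' @inheritParams nearest_distance
#' @param edges Ascending annulus edges in micrometres (>= 2 values;
#'   default 0 to 300 by 30).
#' @return data.frame of class `"radial_profile"`: `lo`, `hi`, `count`,
#'   `density` (the overflow row has `hi = Inf` and `density = NA`), with
#'   attribute `n_objects`.
#' @export
radial_counts <- function(targets, objects, edges = seq(0, 300, by = 30)) {
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be >= 2 ascending values")
  }
  d <- nearest_distance(targets, objects)
  n_obj <- nrow(as_xy(objects))
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  counts <- vapply(seq_along(lo),
                   function(i) sum(d >= lo[i] & d < hi[i]), integer(1))
  overflow <- sum(d >= edges[length(edges)]) + sum(d < edges[1L])
  area <- pi * (hi^2 - lo^2) * n_obj
  out <- data.frame(
    lo = c(lo, edges[length(edges)]),
    hi = c(hi, Inf),
    count = c(counts, overflow),
    density = c(counts / area, NA_real_)
  )
  attr(out, "n_objects") <- n_obj
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d targets around %d niche object(s)\n",
              sum(x$count), attr(x, "n_objects")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a radial count profile
#'
#' @param x A `radial_profile`.
#' @param what `"count"` or `"density"`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.radial_profile <- function(x, what = c("count", "density"), ...) {
  what <- match.arg(what)
  keep <- is.finite(x$hi)
  graphics::barplot(x[[what]][keep],
                    names.arg = sprintf("%g-%g", x$lo[keep], x$hi[keep]),
                    xlab = "distance to nearest niche object (um)",
                    ylab = what, las = 2, ...)
  invisible(x)
}

#' Compare two groups of distances (two-sided unpaired t-test)
#'
#' Welch's unequal-variance t-test by default (Student's pooled-variance
#' variant via `var_equal = TRUE`), as used for pre- vs post-treatment
#' distance comparisons.
#'
#' @param group_a,group_b Numeric distance vectors, each with >= 2 values.
#' @param var_equal Use the pooled-variance Student test (default FALSE =
#'   Welch).
#' @return List: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @examples
#' compare_distances(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_distances <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 values")
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b),
       method = if (var_equal) "student" else "welch")
}

#' Mean nearest distance, pooled and per image
#'
#' Reports the mean of per-cell distances pooled over all cells and, when
#' an image/sample grouping is given, the per-image means and their mean —
#' the two aggregation conventions for "average distance" summaries.
#'
#' @param distances Numeric per-cell distances.
#' @param image Optional grouping factor (image or sample id).
#' @return List: `pooled_mean`, and with grouping `per_image` (named
#'   means) and `mean_of_image_means`.
#' @export
mean_distance <- function(distances, image = NULL) {
  out <- list(pooled_mean = mean(distances))
  if (!is.null(image)) {
    per <- tapply(distances, image, mean)
    out$per_image <- c(per)   # drop the array dim, keep names
    out$mean_of_image_means <- mean(per)
  }
  out
}
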