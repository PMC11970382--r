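## Independent oracles used across test files. These deliberately share no
## code with the package: histograms are built by explicit edge search,
## KL by a scalar loop, and the rank-sum null by exhaustive enumeration.

## 2-D histogram by explicit edge scan (top edge right-inclusive).
oracle_hist2d <- function(x, y, bbox, n_bins) {
  xe <- seq(bbox[1], bbox[2], length.out = n_bins + 1)
  ye <- seq(bbox[3], bbox[4], length.out = n_bins + 1)
  h <- matrix(0, n_bins, n_bins)
  for (s in seq_along(x)) {
    ix <- iy <- n_bins
    for (b in seq_len(n_bins - 1)) {
      if (x[s] >= xe[b] && x[s] < xe[b + 1]) ix <- b
      if (y[s] >= ye[b] && y[s] < ye[b + 1]) iy <- b
    }
    h[iy, ix] <- h[iy, ix] + 1
  }
  h / sum(h)
}

## KL divergence by scalar summation with pseudo-count smoothing.
oracle_kl <- function(p, q, eps = 1e-10) {
  p <- p / sum(p) + eps
  q <- q / sum(q) + eps
  p <- p / sum(p)
  q <- q / sum(q)
  total <- 0
  for (i in seq_along(p)) total <- total + p[i] * log(p[i] / q[i])
  total
}

## Full pairwise KL matrix from scratch: above-average memberships,
## shared-bounding-box histograms, NaN rule for empty memberships.
oracle_coloc_matrix <- function(spots, A, n_bins, eps = 1e-10) {
  bbox <- c(range(spots$x), range(spots$y))
  K <- ncol(A)
  hs <- vector("list", K)
  empty <- logical(K)
  for (k in seq_len(K)) {
    mem <- which(A[, k] > mean(A[, k]))
    if (!length(mem)) {
      empty[k] <- TRUE
    } else {
      hs[[k]] <- as.vector(oracle_hist2d(spots$x[mem], spots$y[mem],
                                         bbox, n_bins))
    }
  }
  kl <- matrix(NaN, K, K, dimnames = list(colnames(A), colnames(A)))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (!empty[i] && !empty[j]) kl[i, j] <- oracle_kl(hs[[i]], hs[[j]], eps)
    }
  }
  kl
}

## Exact two-sided Mann-Whitney p by enumerating every assignment of the
## pooled ranks to group A. Returns p for the observed untied samples.
oracle_rank_sum_exact <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

## Welch t-test from first principles.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
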