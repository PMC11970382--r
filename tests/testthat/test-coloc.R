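make_map <- function(n = 40, K = 3, seed = 1, conc = 1) {
  set.seed(seed)
  spots <- data.frame(spot_id = sprintf("s%03d", seq_len(n)),
                      in_tissue = TRUE, array_row = NA_integer_,
                      array_col = NA_integer_,
                      x = runif(n), y = runif(n))
  A <- matrix(rgamma(n * K, conc), n, K,
              dimnames = list(spots$spot_id,
                              paste0("t", seq_len(K))))
  A <- A / rowSums(A)
  list(spots = spots, A = A)
}

test_that("above-average membership follows the strict-mean rule", {
  expect_equal(assign_spots(c(1, 2, 3, 6)), 4L)           # mean 3, strict >
  expect_equal(assign_spots(rep(5, 4)), integer(0))        # constant: empty
  expect_equal(assign_spots(c(0, 0, 1), mode = "weighted"), c(0, 0, 1))
  expect_error(assign_spots(c(1, NA)), "finite")
  expect_error(assign_spots(c(-1, 1)), "non-negative")
})

test_that("density histograms bin members on the shared grid", {
  spots <- data.frame(spot_id = c("a", "b", "c", "d"),
                      x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  cfg <- run_config(n_bins = 2)
  h <- density_histogram(spots, 1:4, cfg)
  expect_equal(h$mass, rep(0.25, 4))          # one corner per bin
  expect_false(h$empty)
  expect_equal(h$n_members, 4L)

  h1 <- density_histogram(spots, 2L, cfg)
  expect_equal(sum(h1$mass), 1)
  expect_equal(sum(h1$mass == 1), 1L)          # single member -> single bin

  h0 <- density_histogram(spots, integer(0), cfg)
  expect_true(h0$empty)
  expect_true(all(h0$mass == 0))

  degenerate <- data.frame(spot_id = "a", x = 1, y = 1)
  expect_error(density_histogram(degenerate, 1L, cfg), "degenerate geometry")
})

test_that("weighted histograms use abundances as mass", {
  spots <- data.frame(spot_id = c("a", "b", "c", "d"),
                      x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  cfg <- run_config(n_bins = 2, membership_mode = "weighted")
  h <- density_histogram(spots, c(1, 1, 0, 2), cfg)
  expect_equal(sum(h$mass), 1)
  expect_equal(sort(h$mass), c(0, 0.25, 0.25, 0.5))
})

test_that("KL divergence matches closed forms and is epsilon-stable", {
  ## identity: D(P||P) = 0
  set.seed(3)
  for (i in 1:20) {
    p <- rgamma(25, 1)
    expect_lt(abs(kl_divergence(p, p)), 1e-12)
  }
  ## two-bin closed form: 0.75 ln 3 + 0.25 ln(1/3) = 0.5 ln 3
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.25, 0.75)),
               0.5 * log(3), tolerance = 1e-6)
  ## degenerate P: converges to ln 2 as epsilon shrinks
  vals <- vapply(c(1e-6, 1e-8, 1e-10, 1e-12),
                 function(e) kl_divergence(c(1, 0), c(0.5, 0.5), e), 0)
  errs <- abs(vals - log(2))
  expect_true(all(diff(errs) < 0))             # monotone convergence
  expect_lt(errs[4], 1e-10)
  ## non-negativity on random pairs
  set.seed(4)
  for (i in 1:20) {
    p <- rgamma(30, 0.5)
    q <- rgamma(30, 0.5)
    expect_gte(kl_divergence(p, q), 0)
  }
  ## defined KL barely moves between epsilon 1e-10 and 1e-12
  set.seed(5)
  p <- rgamma(50, 1) + 0.05    # full support: stability regime
  q <- rgamma(50, 1) + 0.05
  expect_lt(abs(kl_divergence(p, q, 1e-10) - kl_divergence(p, q, 1e-12)),
            1e-6)
})

test_that("KL refuses mismatched grids and empty histograms", {
  spots <- data.frame(spot_id = letters[1:4],
                      x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  h2 <- density_histogram(spots, 1:4, run_config(n_bins = 2))
  h3 <- density_histogram(spots, 1:4, run_config(n_bins = 3))
  expect_error(kl_divergence(h2, h3), "different bin grids")
  h0 <- density_histogram(spots, integer(0), run_config(n_bins = 2))
  expect_error(kl_divergence(h2, h0), "empty histogram")
})

test_that("Jensen-Shannon divergence is symmetric and bounded by log 2", {
  set.seed(6)
  p <- rgamma(30, 1)
  q <- rgamma(30, 1)
  expect_equal(js_divergence(p, q), js_divergence(q, p), tolerance = 1e-12)
  expect_lte(js_divergence(c(1, 0), c(0, 1)), log(2) + 1e-9)
  expect_lt(abs(js_divergence(p, p)), 1e-12)
})

test_that("the observed KL matrix matches the brute-force oracle", {
  for (seed in 1:3) {
    mp <- make_map(n = 30 + 5 * seed, K = 4, seed = seed)
    for (nb in c(2, 4, 5)) {
      cfg <- run_config(n_bins = nb)
      got <- coloc_matrix(mp$spots, mp$A, cfg)
      want <- oracle_coloc_matrix(mp$spots, mp$A, nb)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("histogram + KL path agrees with the matrix path", {
  mp <- make_map(n = 35, K = 3, seed = 9)
  cfg <- run_config(n_bins = 5)
  bbox <- c(range(mp$spots$x), range(mp$spots$y))
  kl <- coloc_matrix(mp$spots, mp$A, cfg)
  h1 <- density_histogram(mp$spots, assign_spots(mp$A[, 1]), cfg, bbox)
  h2 <- density_histogram(mp$spots, assign_spots(mp$A[, 2]), cfg, bbox)
  expect_equal(kl_divergence(h1, h2, cfg$epsilon), kl[1, 2],
               tolerance = 1e-12)
})

test_that("types without above-average spots yield NaN rows and columns", {
  mp <- make_map(n = 30, K = 3, seed = 2)
  A <- cbind(mp$A, t_const = 0.25)     # constant: nothing above the mean
  kl <- coloc_matrix(mp$spots, A, run_config(n_bins = 4))
  expect_true(all(is.nan(kl[4, ])))
  expect_true(all(is.nan(kl[, 4])))
  expect_false(anyNA(kl[1:3, 1:3]))
  expect_equal(diag(kl)[1:3], c(t1 = 0, t2 = 0, t3 = 0))

  res <- coloc_test(mp$spots, A, run_config(n_perm = 5, n_bins = 4, seed = 1))
  expect_true(all(is.nan(res$pvals[4, ])))
  expect_true(all(is.nan(res$pvals[, 4])))
})

test_that("duplicated type columns are at zero KL distance", {
  mp <- make_map(n = 40, K = 2, seed = 7)
  A <- cbind(mp$A, t_dup = mp$A[, 1])
  kl <- coloc_matrix(mp$spots, A, run_config(n_bins = 4))
  expect_equal(kl[1, 3], 0)
  expect_equal(kl[3, 1], 0)
})

test_that("empirical p-values count the requested tail with plus-one", {
  null <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(empirical_pvalue(0.25, null, "as_written"), 3 / 5)  # 2 above
  expect_equal(empirical_pvalue(0.25, null, "co_localization"), 3 / 5)
  expect_equal(empirical_pvalue(0.99, null, "as_written"), 1 / 5)  # boundary
  expect_equal(empirical_pvalue(0.01, null, "as_written"), 1)
  expect_true(is.nan(empirical_pvalue(NaN, null)))
})

test_that("the permutation null is reproducible and sized as configured", {
  mp <- make_map(n = 30, K = 3, seed = 5)
  cfg <- run_config(n_perm = 7, n_bins = 4, seed = 123)
  n1 <- permutation_null(mp$spots, mp$A, cfg)
  n2 <- permutation_null(mp$spots, mp$A, cfg)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(7L, 3L, 3L))
  expect_false(anyNA(n1[, 1, 2]))

  one <- permutation_null(mp$spots, mp$A,
                          run_config(n_perm = 1, n_bins = 4, seed = 1))
  expect_equal(dim(one)[1], 1L)

  tiny <- make_map(n = 4, K = 2, seed = 1)
  expect_error(
    permutation_null(tiny$spots, tiny$A,
                     run_config(subsample_frac = 0.25, n_perm = 2)),
    "subsample smaller than 2"
  )
})

test_that("the full co-localization result is a pure function of inputs", {
  mp <- make_map(n = 40, K = 3, seed = 8)
  cfg <- run_config(n_perm = 20, n_bins = 5, seed = 11)
  r1 <- coloc_test(mp$spots, mp$A, cfg)
  r2 <- coloc_test(mp$spots, mp$A, cfg)
  expect_identical(r1, r2)
  ## p-values live in [1/(n_perm+1), 1]
  ok <- !is.na(r1$pvals)
  expect_true(all(r1$pvals[ok] >= 1 / 21 - 1e-12))
  expect_true(all(r1$pvals[ok] <= 1))
  ## both tails stored; configured tail populates pvals
  expect_identical(r1$pvals, r1$pvals_as_written)
  ## summary is ordered by KL and covers each unordered pair once
  s <- summary(r1)
  expect_equal(nrow(s), 3L)
  expect_true(!is.unsorted(s$kl_ab))
})

test_that("out-of-tissue spots are excluded unless requested", {
  mp <- make_map(n = 40, K = 3, seed = 10)
  mp$spots$in_tissue[1:10] <- FALSE
  cfg <- run_config(n_bins = 4)
  kl_drop <- coloc_matrix(mp$spots, mp$A, cfg)
  kl_all <- coloc_matrix(mp$spots, mp$A, cfg, include_out_of_tissue = TRUE)
  want <- oracle_coloc_matrix(mp$spots[-(1:10), ], mp$A[-(1:10), ], 4)
  expect_equal(kl_drop, want, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(kl_drop, kl_all)))
})

test_that("coloc results print and plot without error", {
  mp <- make_map(n = 40, K = 3, seed = 12)
  r <- coloc_test(mp$spots, mp$A, run_config(n_perm = 10, n_bins = 5, seed = 2))
  expect_output(print(r), "3 cell types")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(r, pair = c("t1", "t2")))
})
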