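test_that("depth normalization is scale-invariant and matches hand values", {
  ## hand 2x2 case: spots s1 (counts 1, 3) and s2 (counts 2, 6)
  counts <- matrix(c(1, 3, 2, 6), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_expression(counts)
  ## libraries 4 and 8, median 6: s1 -> (1.5, 4.5), s2 -> (1.5, 4.5)
  want <- log1p(matrix(c(1.5, 1.5, 4.5, 4.5), 2, 2,
                       dimnames = list(c("s1", "s2"), c("g1", "g2"))))
  expect_equal(norm, want, ignore_attr = TRUE)
  ## doubling a spot's counts leaves its normalized profile unchanged
  expect_equal(norm["s1", ], norm["s2", ])

  ## equal depths: normalization is the identity up to log1p
  eq <- matrix(c(3, 1, 2, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(normalize_expression(eq), log1p(t(eq)), ignore_attr = TRUE)
})

test_that("zero-library spots are flagged and scored as NaN", {
  counts <- matrix(c(2, 2, 0, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_warning(norm <- normalize_expression(counts), "zero library")
  expect_equal(attr(norm, "zero_library"), "s2")
  expect_true(all(is.nan(norm["s2", ])))
  expect_false(anyNA(norm["s1", ]))
})

test_that("ROI masks implement the strict above-average rule", {
  m <- define_roi(c(1, 2, 3, 6))
  expect_equal(as.logical(m), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(m, "threshold"), 3)
  expect_warning(empty <- define_roi(c(5, 5, 5)), "empty ROI")
  expect_false(any(empty))
  single <- define_roi(c(0, 0, 7, 0))
  expect_equal(which(as.logical(single)), 3L)
  expect_error(define_roi(c(1, Inf)), "finite")
})

test_that("ROI size and the above-average proportion are two views of one rule", {
  expect_equal(proportion_above_average(c(1, 2, 3, 6)), 0.25)
  expect_equal(proportion_above_average(rep(2, 5)), 0)
  expect_equal(proportion_above_average(c(0, 10)), 0.5)
  set.seed(31)
  for (i in 1:200) {
    a <- switch(1 + i %% 4,
                rgamma(20, 0.5),
                rpois(15, 3),
                runif(50),
                rep(round(runif(4), 2), each = 3))
    n_in <- suppressWarnings(sum(define_roi(a)))
    expect_equal(proportion_above_average(a) * length(a), n_in)
  }
})

toy_expr <- function() {
  ## 3 spots x 6 genes; means order g1 < g2 < ... < g6
  m <- rbind(c(0.5, 1.0, 1.1, 4.0, 5.0, 9.0),
             c(0.6, 1.0, 1.2, 4.2, 5.1, 9.3),
             c(0.7, 1.0, 1.3, 4.4, 5.2, 9.6))
  dimnames(m) <- list(c("s1", "s2", "s3"), paste0("g", 1:6))
  m
}

test_that("signature scores subtract expression-matched controls", {
  ## identical genes -> zero score regardless of the control draw
  flat <- matrix(2, 4, 30,
                 dimnames = list(paste0("s", 1:4), paste0("g", 1:30)))
  sc <- signature_score(flat, c("g3", "g7"), seed = 1)
  expect_true(all(abs(sc) < 1e-9))

  ## 6-gene toy, 2 bins of 3: signature g1 sits in the low bin with g2, g3;
  ## g2 and g3 are constant 1.0 and (1.0, 1.2, 1.3)... make them equal so
  ## the control mean is draw-independent, then hand-compute.
  m <- toy_expr()
  m[, "g3"] <- m[, "g2"]            # both controls now equal per spot
  sc <- signature_score(m, "g1", n_bins_ctrl = 2, n_ctrl_per_gene = 10,
                        seed = 7)
  expect_equal(as.numeric(sc), unname(m[, "g1"] - m[, "g2"]),
               tolerance = 1e-12)

  ## determinism under a fixed seed
  big <- matrix(rgamma(100 * 50, 2), 100, 50,
                dimnames = list(NULL, paste0("g", 1:50)))
  s1 <- signature_score(big, c("g5", "g10"), seed = 3)
  s2 <- signature_score(big, c("g5", "g10"), seed = 3)
  expect_identical(s1, s2)
})

test_that("signature scoring validates its gene set", {
  m <- toy_expr()
  expect_error(signature_score(m, c("g1", "nope")), "nope")
  m[, "g1"] <- 0
  expect_warning(sc <- signature_score(m, c("g1", "g4"), seed = 1),
                 "zero-expression")
  expect_error(suppressWarnings(signature_score(m, "g1", seed = 1)),
               "empty gene set")
})

test_that("random in-bin gene sets score near zero on average", {
  set.seed(17)
  expr <- matrix(rgamma(150 * 200, 2, 1), 150, 200,
                 dimnames = list(NULL, sprintf("g%03d", 1:200)))
  means <- colMeans(expr)
  bin <- ceiling(rank(means, ties.method = "first") / (200 / 25))
  in_bin <- colnames(expr)[bin == 13]
  draws <- vapply(1:200, function(i) {
    gs <- sample(in_bin, 3)
    mean(signature_score(expr, gs, seed = i))
  }, 0)
  expect_lt(abs(mean(draws)), 0.05)
})

test_that("ligand-receptor co-expression is the per-spot mean of the pair", {
  m <- toy_expr()
  sc <- lr_coexpression(m, "g2", "g4")
  expect_equal(as.numeric(sc), unname((m[, "g2"] + m[, "g4"]) / 2))
  expect_equal(as.numeric(lr_coexpression(m, "g5", "g5")),
               unname(m[, "g5"]))
  expect_equal(as.numeric(lr_coexpression(m * 0, "g1", "g2")),
               rep(0, 3))
  expect_error(lr_coexpression(m, "g1", "missing_gene"), "missing_gene")
})

test_that("in/out-ROI comparison matches exact enumeration on small samples", {
  r <- compare_in_out(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$p_value, 1 / 3)   # all C(4,2) = 6 rank splits
  expect_equal(r$method, "exact")
  expect_equal(r$median_in, 1.5)
  expect_equal(r$n_out, 2L)

  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    v <- sample(seq(0.01, 1, by = 0.01), n1 + n2)   # untied
    got <- compare_in_out(v, c(rep(TRUE, n1), rep(FALSE, n2)))
    expect_equal(got$p_value, oracle_rank_sum_exact(v[1:n1], v[-(1:n1)]),
                 tolerance = 1e-12)
  }
})

test_that("identical groups and strong shifts behave at the extremes", {
  same <- compare_in_out(rep(c(1, 2, 3), 2),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$p_value, 1)
  set.seed(29)
  x <- c(rnorm(50, 3), rnorm(50, 0))
  shifted <- compare_in_out(x, c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_lt(shifted$p_value, 1e-6)
  expect_equal(shifted$method, "normal_approx")
  expect_error(compare_in_out(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})
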