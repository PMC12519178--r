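test_that("Pearson correlation handles exact relations and degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, x + 1), 1)
  expect_error(pearson_r(rep(1, 4), x), "zero variance")
  expect_error(pearson_r(x, c(1, 2)), "equal length")
  expect_error(pearson_r(x, c(1, 2, NA, 4)), "missing")
})

test_that("Lin's CCC matches a brute-force moment computation", {
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2.5 / 3.5)
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.714286,
               tolerance = 1e-6)
  # reversing y flips the covariance without a location shift: exactly -1
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  # reversed and shifted by +1: brute force gives -2.5/3.5
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(5, 4, 3, 2)), -0.714286,
               tolerance = 1e-6)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:60, 1)
    x <- rnorm(n, 10, 3); y <- 0.8 * x + rnorm(n, 1, 1)
    expect_equal(lin_ccc(x, y), brute_ccc(x, y), tolerance = 1e-13)
  }
  expect_error(lin_ccc(rep(2, 5), rep(2, 5)), "undefined")
})

test_that("CCC is bounded by Pearson's correlation and is affine-invariant", {
  set.seed(3)
  for (i in 1:50) {
    p <- rbvn_pairs(30, rho = runif(1, -0.9, 0.9))
    p$y <- p$y + rnorm(1, 0, 3)  # random location shift
    ccc <- lin_ccc(p$x, p$y)
    expect_lte(abs(ccc), abs(pearson_r(p$x, p$y)) + 1e-14)
    # same positive affine map applied to both vectors leaves CCC unchanged
    expect_equal(lin_ccc(2.3 * p$x + 5, 2.3 * p$y + 5), ccc, tolerance = 1e-12)
  }
  x <- rnorm(20)
  expect_equal(lin_ccc(x, x), 1)
})

test_that("agreement classification has exactly the two printed breakpoints", {
  expect_equal(classify_agreement(0.996), "excellent")
  expect_equal(classify_agreement(0.152), "poor")
  expect_equal(classify_agreement(0.431), "fair to good")
  # boundary values belong to the lower class
  expect_equal(classify_agreement(0.40), "poor")
  expect_equal(classify_agreement(0.75), "fair to good")
  sweep <- classify_agreement(seq(-1, 1, by = 0.001))
  expect_setequal(unique(sweep), c("poor", "fair to good", "excellent"))
  expect_equal(sum(rle(sweep)$lengths > 0), 3)  # piecewise-constant, 3 runs
  expect_error(classify_agreement(1.2), "\\[-1, 1\\]")
})

test_that("CCC confidence interval brackets the estimate and stays in (-1,1)", {
  set.seed(5)
  for (i in 1:20) {
    p <- rbvn_pairs(sample(10:80, 1), rho = runif(1, 0.2, 0.95))
    res <- ccc_confidence_interval(p$x, p$y)
    expect_lt(res$ci_low, res$ccc)
    expect_gt(res$ci_high, res$ccc)
    expect_gt(res$ci_low, -1)
    expect_lt(res$ci_high, 1)
    expect_equal(res$agreement_class, classify_agreement(res$ccc))
    expect_equal(res$pearson, pearson_r(p$x, p$y))
  }
  x <- rnorm(10)
  expect_error(ccc_confidence_interval(x, x), "degenerate")
})

test_that("dependent-CCC comparison separates perfect from noisy predictors", {
  set.seed(9)
  common <- rnorm(40, 12, 2)
  noisy <- common + rnorm(40, 0, 1.5)
  res <- compare_dependent_ccc(common, common, noisy, n_boot = 500, seed = 1)
  expect_gt(res$delta, 0)
  expect_gt(res$ci_low, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$ccc_a, 1)

  self <- compare_dependent_ccc(common, noisy, noisy, n_boot = 500, seed = 2)
  expect_equal(self$delta, 0)
  expect_lte(self$ci_low, 0)
  expect_gte(self$ci_high, 0)
  expect_gt(self$p_value, 0.9)

  # fixed seed => identical bootstrap inference; different seed => different CI
  again <- compare_dependent_ccc(common, common, noisy, n_boot = 500, seed = 1)
  expect_identical(res[c("delta", "ci_low", "ci_high", "p_value")],
                   again[c("delta", "ci_low", "ci_high", "p_value")])
  expect_error(compare_dependent_ccc(common, common, noisy, n_boot = 500),
               "seed")
})

test_that("mean-difference test covers paired and independent designs", {
  x <- c(1, 2, 3)
  # constant +1 shift: exact mean contrast, undefined t reported as such
  expect_warning(res <- mean_diff_test(x + 1, x, paired = TRUE), "constant")
  expect_equal(res$mean_x - res$mean_y, 1)
  expect_true(is.na(res$t_statistic))
  expect_error(mean_diff_test(x, x, paired = TRUE), "zero variance")
  expect_error(mean_diff_test(1:5, 1:4, paired = TRUE), "equal length")

  set.seed(21)
  a <- rnorm(30, 10, 2); b <- rnorm(30, 10, 2)
  ind <- mean_diff_test(a, b, paired = FALSE)
  expect_equal(ind$df, 58)  # pooled-variance Student's t
  expect_equal(ind$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_false(ind$paired)
})
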