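test_that("cohort spec validates its parameters", {
  expect_s3_class(cohort_profile("swine"), "cohort_spec")
  expect_equal(cohort_profile("swine")$n, 24L)
  expect_equal(cohort_profile("patient")$mean_dmax, 22.07)
  expect_equal(cohort_profile("patient", n = 10)$n, 10L)
  expect_error(cohort_spec(2, 15, 2, 9, 2), "at least 3")
  expect_error(cohort_spec(10, -1, 2, 9, 2), "positive")
  expect_error(cohort_spec(10, 15, 2, 9, 2, rho = 1), "rho")
  expect_error(cohort_spec(10, 15, 2, 9, 2, anisotropy = 0.6), "anisotropy")
  expect_error(cohort_spec(10, 15, 2, 9, 2, edge_sd = -0.1), "non-negative")
})

test_that("noiseless circularization collapses post diameters onto d_eq", {
  spec <- cohort_profile("swine", anisotropy = 0, remodel_sd = 0,
                         edge_sd = 0, seed = 4)
  tab <- simulate_cohort(spec)
  expect_equal(tab$post_dmax_mm, tab$true_deq_mm)
  expect_equal(tab$post_dmin_mm, tab$true_deq_mm)
  expect_equal(tab$pre_max_x1_mm, tab$pre_max_x2_mm)
  # true_deq is the deterministic circle-fit of the latent diameters
  expect_equal(tab$true_deq_mm,
               predict_equivalent_diameter(tab$dmax_mm, tab$dmin_mm)$d_eq)
})

test_that("simulation is bit-identical for a fixed spec and seeded sanely", {
  spec <- cohort_profile("swine", seed = 123)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  expect_false(identical(simulate_cohort(cohort_profile("swine", seed = 124)),
                         simulate_cohort(spec)))
  # the caller's RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated moments and correlation match the spec", {
  tab <- simulate_cohort(cohort_profile("swine", seed = 2))
  # sampling-distribution bound: |mean - mu| < 3 * sd / sqrt(n)
  expect_lt(abs(mean(tab$dmax_mm) - 15.52), 3 * 2.82 / sqrt(24))
  expect_lt(abs(mean(tab$dmin_mm) - 8.88), 3 * 2.01 / sqrt(24))
  expect_true(all(tab$dmax_mm > tab$dmin_mm))
  expect_true(all(tab$dmin_mm > 1))

  big <- simulate_cohort(cohort_profile("swine", n = 1e5, seed = 3))
  expect_lt(abs(cor(big$dmax_mm, big$dmin_mm) - 0.5), 0.02)
  # edge averaging recovers each diameter exactly
  expect_equal(mean_edge_diameter(big$pre_max_x1_mm, big$pre_max_x2_mm),
               big$dmax_mm)
  expect_equal(mean_edge_diameter(big$post_min_x1_mm, big$post_min_x2_mm),
               big$post_dmin_mm)
})

test_that("post-placement cross-section circularizes as noise vanishes", {
  ccc_post <- function(alpha, rsd) {
    tab <- simulate_cohort(cohort_profile("swine", n = 200, anisotropy = alpha,
                                          remodel_sd = rsd, seed = 8))
    lin_ccc(tab$post_dmax_mm, tab$post_dmin_mm)
  }
  expect_gt(ccc_post(0.005, 0.1), ccc_post(0.02, 0.5))
  expect_gt(ccc_post(0.001, 0.01), 0.999)
})

test_that("cohort summary reports mean/SD per variable and group contrasts", {
  spec <- cohort_profile("swine", anisotropy = 0, remodel_sd = 0,
                         edge_sd = 0, seed = 5)
  tab <- simulate_cohort(spec)
  s <- summarize_cohort(tab)
  expect_equal(s$variable,
               c("dmax_mm", "dmin_mm", "deq_mm", "post_dmax_mm", "post_dmin_mm"))
  # noiseless circularization: mean post D_max equals mean D_eq exactly
  expect_equal(s$mean[s$variable == "post_dmax_mm"],
               s$mean[s$variable == "deq_mm"])
  expect_equal(s$sd[s$variable == "dmax_mm"], sd(tab$dmax_mm))

  # two identical subjects => zero SD everywhere
  two <- tab[c(1, 1), ]
  expect_equal(summarize_cohort(two)$sd, rep(0, 5))
  expect_error(summarize_cohort(tab[1, ]), "at least 2")

  g <- rep(c("phi32", "phi20"), each = 12)
  sg <- summarize_cohort(tab, group = g)
  expect_true(all(c("mean_phi20", "sd_phi32", "p_value") %in% names(sg)))
  expect_true(all(sg$p_value > 0 & sg$p_value <= 1))
  expect_error(summarize_cohort(tab, group = rep("a", 24)), "two groups")
})

test_that("a pathological spec hits the rejection cap with a clear error", {
  bad <- cohort_profile("swine", mean_dmax = 1.01, sd_dmax = 1e-6,
                        mean_dmin = 50, sd_dmin = 1e-6, rho = 0, seed = 1)
  expect_error(simulate_cohort(bad), "rejection cap")
})
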