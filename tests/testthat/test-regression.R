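test_that("an exact linear bias field gives r-squared of one", {
  sites <- simulate_electrode_cohort(n = 10, direction = c(0, 1, 0),
                                     gradient = 2, noise_sd = 0, seed = 21)
  fit <- bias_position_regression(sites, "init_bias", "left")
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$df, c(3, 6))
  expect_equal(unname(fit$beta["x"]), 0, tolerance = 1e-9)
})

test_that("a position-independent bias has null-level r-squared", {
  set.seed(22)
  r2 <- replicate(60, {
    sites <- simulate_electrode_cohort(n = 50, direction = c(0, 1, 0),
                                       gradient = 0, noise_sd = 1)
    bias_position_regression(sites, "init_bias", "left")$r2
  })
  expect_lt(abs(mean(r2) - 3 / 49), 0.02)  # E[r2] = p/(n-1) under null
})

test_that("fits are invariant to bias rescaling and coordinate translation", {
  sites <- simulate_electrode_cohort(n = 12, direction = c(0.6, 0.8, 0),
                                     gradient = 1, noise_sd = 0.4, seed = 23)
  f1 <- bias_position_regression(sites, "init_bias", "left")
  scaled <- sites; scaled$init_bias <- 5 * scaled$init_bias - 2
  f2 <- bias_position_regression(scaled, "init_bias", "left")
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
  moved <- sites; moved$x <- moved$x + 10; moved$z <- moved$z - 4
  f3 <- bias_position_regression(moved, "init_bias", "left")
  expect_equal(f1$r2, f3$r2, tolerance = 1e-12)
})

test_that("incomplete sites are excluded listwise and degenerate designs refused", {
  sites <- simulate_electrode_cohort(n = 8, seed = 24)
  sites$x[3] <- NA
  fit <- bias_position_regression(sites, "init_bias", "left")
  expect_equal(fit$n, 7)
  expect_equal(fit$excluded_ids, 3)

  flat <- simulate_electrode_cohort(n = 8, seed = 25)
  flat$init_bias <- 1
  expect_error(bias_position_regression(flat, "init_bias", "left"),
               "zero variance")

  collinear <- simulate_electrode_cohort(n = 8, seed = 26)
  collinear$z <- 2 * collinear$x
  expect_error(bias_position_regression(collinear, "init_bias", "left"),
               "singular")
})

test_that("the packaged left-side first-fixation bias depends on position", {
  sites <- load_electrode_sites()
  fit <- bias_position_regression(sites, "init_bias", "left")
  expect_equal(fit$n, 13)                    # patient 17 lacks coordinates
  expect_equal(fit$excluded_ids, 17)
  expect_equal(round(fit$r2, 2), 0.56)
  expect_equal(fit$df, c(3, 9))
  ax <- principal_bias_axis(fit, sites)
  # bias changes most along the posterior-anterior (y) axis
  expect_equal(ax$ranked_axes[1], "y")
})

test_that("the principal axis recovers a generating direction", {
  truth <- c(0, 1, 0)
  sites <- simulate_electrode_cohort(n = 30, direction = truth, gradient = 1,
                                     noise_sd = 0, seed = 27)
  fit <- bias_position_regression(sites, "init_bias", "left")
  ax <- principal_bias_axis(fit, sites)
  expect_equal(abs(sum(ax$direction * truth)), 1, tolerance = 1e-9)
  expect_equal(unname(ax$line(2) - ax$centroid), 2 * unname(ax$direction))

  # noisy recovery: axis within 15 degrees of truth in most replicates
  set.seed(28)
  angles <- replicate(20, {
    s <- simulate_electrode_cohort(n = 50, direction = truth, gradient = 1,
                                   noise_sd = 0.4)
    f <- bias_position_regression(s, "init_bias", "left")
    a <- principal_bias_axis(f, s)
    acos(pmin(1, abs(sum(a$direction * truth)))) * 180 / pi
  })
  expect_gte(mean(angles <= 15), 0.9)

  null_fit <- fit; null_fit$beta[] <- 0
  expect_true(principal_bias_axis(null_fit, sites)$undefined)
})

test_that("condition-difference regressions isolate stimulation-induced change", {
  sites <- simulate_electrode_cohort(n = 12, direction = c(0, 1, 0),
                                     gradient = 1, noise_sd = 0, seed = 29)
  off_bias <- rep(0.5, 12)
  cond_bias <- sites$init_bias + off_bias
  fit <- condition_difference_regression(sites, cond_bias, off_bias, "left")
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  expect_error(condition_difference_regression(sites, off_bias, off_bias,
                                               "left"), "zero variance")

  # only the stimulated condition carries the gradient: the difference
  # regression beats the baseline regression
  set.seed(30)
  base_noise <- rnorm(12, 0, 1)
  s2 <- sites
  s2$init_bias <- base_noise                       # baseline: no gradient
  f_off <- bias_position_regression(s2, "init_bias", "left")
  f_diff <- condition_difference_regression(
    sites, sites$init_bias + base_noise + rnorm(12, 0, 0.1), base_noise,
    "left")
  expect_gt(f_diff$r2, f_off$r2)
})
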