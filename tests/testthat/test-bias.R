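test_that("first-fixation bias is the median over trials", {
  trs <- list(fix_trial(c(-1, 5)), fix_trial(c(0, 5)), fix_trial(c(1, 5)))
  expect_equal(first_fixation_bias(trs), 0)

  shifted <- lapply(1:5, function(k) fix_trial(c(0.14, k)))
  expect_equal(first_fixation_bias(shifted), 0.14)

  # a held pre-stimulus fixation is skipped when configured
  held <- list(fix_trial(c(0, 0.7, 3)))
  expect_equal(first_fixation_bias(held), 0)
  expect_equal(first_fixation_bias(held, bias_config(skip = 1)), 0.7)
})

test_that("global horizontal bias is a signed median with exact antisymmetry", {
  sym <- list(fix_trial(c(9, -2, 2)), fix_trial(c(9, -4, 4, 0)))
  expect_equal(global_horizontal_bias(sym), 0)

  shifted <- lapply(sym, function(tr) {
    tr$fixations$x <- tr$fixations$x + 0.89
    s <- tr$saccades; s$x0 <- s$x0 + 0.89; s$x1 <- s$x1 + 0.89
    trial(tr$subject_id, tr$condition, tr$image_id, tr$fixations,
          s[, c("t_start", "t_end", "x0", "y0", "x1", "y1",
                "peak_velocity")], tr$duration)
  })
  expect_equal(global_horizontal_bias(shifted), 0.89)

  asym <- list(fix_trial(c(0, -1, 2, 5)), fix_trial(c(0, 3, 1)))
  expect_equal(global_horizontal_bias(lapply(asym, mirror_trial)),
               -global_horizontal_bias(asym))
  # pooled option pools post-first fixations before the median
  expect_equal(global_horizontal_bias(asym, pooled = TRUE),
               median(c(-1, 2, 5, 3, 1)))
})

test_that("density maps conserve duration mass and split Gaussians exactly", {
  one <- fix_trial(c(0, 0.5), dur = c(300, 1000))
  dm <- build_density_map(one)
  expect_equal(dm$total_mass, 1000, tolerance = 1e-9)   # first fix excluded

  mid <- fix_trial(c(9, 0), dur = c(300, 777))
  dmm <- build_density_map(mid)
  frac <- scanbias:::.hemifield_fraction(dmm, "x")
  expect_equal(frac, 0.5, tolerance = 1e-6)

  right <- fix_trial(c(9, 1), dur = c(300, 500))
  fr <- scanbias:::.hemifield_fraction(build_density_map(right), "x")
  expect_equal(fr, pnorm(2), tolerance = 1e-6)

  expect_error(bias_config(kernel_sd = 0), "kernel_sd")
})

test_that("right-hemifield fraction reproduces the Gaussian-CDF oracle", {
  cfg <- bias_config(include_first = TRUE)
  tr <- fix_trial(c(-1, 1), dur = c(1000, 3000))
  oracle <- (3000 * pnorm(2) + 1000 * (1 - pnorm(2))) / 4000
  expect_equal(right_exploration_fraction(list(tr), cfg), oracle,
               tolerance = 1e-6)

  sym <- list(fix_trial(c(9, -2, 2), dur = c(100, 500, 500)))
  expect_equal(right_exploration_fraction(sym), 0.5, tolerance = 1e-9)

  # fractions mirror to their complement
  expect_equal(right_exploration_fraction(lapply(list(tr), mirror_trial), cfg),
               1 - oracle, tolerance = 1e-6)

  # invariant under uniform duration rescaling
  scaled <- fix_trial(c(-1, 1), dur = c(2500, 7500))
  expect_equal(right_exploration_fraction(list(scaled), cfg), oracle,
               tolerance = 1e-9)
})

test_that("trialwise fractions agree with the full density-map computation", {
  set.seed(81)
  cfg <- bias_config()
  for (k in 1:5) {
    tr <- simulate_trial(scanpath_model(horizontal_bias = runif(1, -1, 1)))
    expect_equal(scanbias:::.trial_hemifield_fraction(tr, cfg, "x"),
                 scanbias:::.hemifield_fraction(build_density_map(tr, cfg), "x"),
                 tolerance = 1e-12)
  }
})

test_that("fractions are resolution-independent", {
  set.seed(82)
  tr <- simulate_trial(scanpath_model())
  f1 <- right_exploration_fraction(list(tr), bias_config(cell = 0.1))
  f2 <- right_exploration_fraction(list(tr), bias_config(cell = 0.05))
  expect_lt(abs(f1 - f2), 1e-3)
})

test_that("vertical bias mirrors the horizontal measures", {
  sym <- list(fix_trial(c(9, 1, -1), y = c(0, 2, -2)))
  v <- vertical_bias(sym)
  expect_equal(v$upper_fraction, 0.5, tolerance = 1e-9)
  expect_equal(v$median_y, 0)

  upper <- list(fix_trial(c(9, 0, 1), y = c(0, 6, 8)))
  expect_gt(vertical_bias(upper)$upper_fraction, 0.99)

  flip <- lapply(sym, function(tr) {
    tr$fixations$y <- -(tr$fixations$y + 1)
    trial(tr$subject_id, tr$condition, tr$image_id, tr$fixations,
          no_saccades(), tr$duration)
  })
  expect_equal(vertical_bias(flip)$median_y, -1)
})

test_that("bias summaries collect all measures per subject-condition", {
  m <- scanpath_model(n_trials = 5, horizontal_bias = 0.9)
  set.seed(91)
  trs <- lapply(1:5, function(k) simulate_trial(m, subject_id = "P02",
                                                condition = "veL"))
  row <- bias_summary(trs)
  expect_equal(row$condition, "veL")
  expect_true(row$right_fraction > 0 && row$right_fraction < 1)
  expect_equal(row$global_horizontal_bias, global_horizontal_bias(trs))
})
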