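test_that("a fixed seed reproduces a trial bit-identically", {
  m <- scanpath_model()
  t1 <- simulate_trial(m, seed = 123)
  t2 <- simulate_trial(m, seed = 123)
  expect_identical(t1, t2)
  t3 <- simulate_trial(m, seed = 124)
  expect_false(identical(t1$fixations, t3$fixations))
})

test_that("generated trials satisfy the event-model invariants", {
  m <- scanpath_model(amplitude_mean = 2.79, horizontal_bias = 0.89,
                      first_fixation_bias = 0.14)
  set.seed(5)
  for (k in 1:20) {
    tr <- simulate_trial(m)
    expect_silent(validate_trial(tr))
    expect_true(all(abs(tr$fixations$x) <= m$bounds[1] / 2))
    expect_true(all(abs(tr$fixations$y) <= m$bounds[2] / 2))
    expect_lte(max(tr$fixations$t_end, tr$saccades$t_end), m$trial_duration)
  }
})

test_that("an unbiased model produces a symmetric fixation distribution", {
  m <- scanpath_model(horizontal_bias = 0, first_fixation_bias = 1e-9)
  set.seed(11)
  trs <- lapply(1:600, function(k) simulate_trial(m))
  mx <- vapply(trs, function(tr) mean(tr$fixations$x), 0)
  # trial means are i.i.d.; the grand mean must sit at 0 within 3 s.e.
  se <- sd(mx) / sqrt(length(mx))
  expect_lt(abs(mean(mx)), 3 * se + 1e-12)
})

test_that("the amplitude law's mean is recovered from generated saccades", {
  m <- scanpath_model(amplitude_mean = 2.79)
  set.seed(13)
  trs <- lapply(1:400, function(k) simulate_trial(m))
  tm <- vapply(trs, function(tr) mean(tr$saccades$amplitude), 0)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2.79), 2 * se)
  expect_gt(sum(vapply(trs, function(tr) nrow(tr$saccades), 0L)), 8000)
})

test_that("infeasible bounds are refused", {
  expect_error(scanpath_model(amplitude_mean = 4, bounds = c(6, 6)),
               "infeasible")
  expect_error(scanpath_model(amplitude_sdlog = 0), "positive")
})

test_that("cohort simulation is seeded, complete and degenerate-safe", {
  spec <- cohort_spec(n_patients = 3, n_controls = 2, n_two_condition = 1,
                      base_model = scanpath_model(n_trials = 2))
  c1 <- simulate_cohort(spec, seed = 9)
  c2 <- simulate_cohort(spec, seed = 9)
  expect_identical(c1, c2)
  # 2 patients x 4 conditions + 1 patient x 2 + 2 controls x 2 runs
  expect_equal(nrow(c1), 2 * 4 + 2 + 2 * 2)
  two_cond <- c1[c1$subject_id == "P03", ]
  expect_setequal(two_cond$condition, c("OFF", "ON"))

  empty_pat <- simulate_cohort(cohort_spec(n_patients = 0, n_controls = 2,
                                           n_two_condition = 0,
                                           base_model = scanpath_model(n_trials = 1)),
                               seed = 1)
  expect_true(all(empty_pat$group == "control"))
  expect_equal(nrow(empty_pat), 4)
})

test_that("rendered samples honour the event structure", {
  g <- screen_geometry()
  one_fix <- fix_trial(0.5, 1.2, dur = 800)
  sam <- render_samples(one_fix, g, noise_sd = 0)
  expect_true(all(sam$x == 0.5 & sam$y == 1.2))
  expect_equal(nrow(sam), 900 / (1000 / g$sampling_rate_hz))

  # slow large saccade so the 500 Hz raster samples the profile densely
  tr <- trial("s", "OFF", "i",
              fixations = data.frame(t_start = c(0, 1400),
                                     t_end = c(1000, 2400),
                                     x = c(-5, 5), y = c(0, 0)),
              saccades = data.frame(t_start = 1000, t_end = 1400,
                                    x0 = -5, y0 = 0, x1 = 5, y1 = 0,
                                    peak_velocity = 2 * 10 / 0.4),
              duration = 2400)
  sam <- render_samples(tr, g, noise_sd = 0)
  sel <- sam$t >= 1000 & sam$t <= 1400
  sp <- sqrt(diff(sam$x)^2 + diff(sam$y)^2) / (1000 / g$sampling_rate_hz) * 1000
  # integral of rendered speed equals the amplitude within 1%
  path_len <- sum(sp[sel[-1]]) * (1 / g$sampling_rate_hz)
  expect_lt(abs(path_len - 10) / 10, 0.01)
  # peak rendered speed within 2% of the event's peak velocity
  expect_lt(abs(max(sp) - 50) / 50, 0.02)
})

test_that("blink windows invalidate samples at the injected fraction", {
  g <- screen_geometry()
  tr <- fix_trial(c(0, 2), dur = c(2000, 2000))
  blinks <- data.frame(t_start = c(500, 3000), t_end = c(700, 3205))
  sam <- render_samples(tr, g, noise_sd = 0.05, blink_windows = blinks)
  injected <- (200 + 205) / (max(sam$t) + 2)
  expect_lt(abs(mean(!sam$valid) - injected), 0.01)
  expect_true(all(is.na(sam$x[!sam$valid])))
})

test_that("electrode cohorts carry the configured linear gradient", {
  sites <- simulate_electrode_cohort(n = 12, direction = c(0, 1, 0),
                                     gradient = 0.8, noise_sd = 0, seed = 4)
  fit <- bias_position_regression(sites, "init_bias", "left")
  expect_equal(fit$r2, 1)

  null_sites <- simulate_electrode_cohort(n = 200, direction = c(0, 1, 0),
                                          gradient = 0, noise_sd = 1,
                                          seed = 5)
  fit0 <- bias_position_regression(null_sites, "init_bias", "left")
  expect_lt(fit0$r2, 0.08)

  expect_error(simulate_electrode_cohort(n = 4), "too few")
  expect_error(simulate_electrode_cohort(direction = c(1, 1, 0)), "unit")
})
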