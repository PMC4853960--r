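test_that("saccade length statistics follow the arithmetic definitions", {
  expect_equal(saccade_length_stats(list(sacc_trial(c(2, 4)))), 3)
  expect_equal(saccade_length_stats(list(sacc_trial(5))), 5)
  expect_true(is.na(saccade_length_stats(list(fix_trial(0)))))
  # pooled vs per-trial aggregation differ under unequal trial sizes
  trs <- list(sacc_trial(c(1, 1, 1, 1)), sacc_trial(3))
  expect_equal(saccade_length_stats(trs), (4 * 1 + 3) / 5)
  expect_equal(saccade_length_stats(trs, per_trial = TRUE), 2)
})

test_that("within-trial MAD is the unscaled median absolute deviation", {
  expect_equal(within_trial_length_mad(list(sacc_trial(c(2, 2, 2)))), 0)
  expect_equal(within_trial_length_mad(list(sacc_trial(c(1, 2, 3)))), 1)
  expect_equal(within_trial_length_mad(list(sacc_trial(c(1, 1, 5)))), 0)
  # subject value is the median of trialwise MADs; 1-saccade trials skipped
  trs <- list(sacc_trial(c(1, 2, 3)), sacc_trial(c(2, 2, 2)), sacc_trial(7),
              sacc_trial(c(0.5, 1.5, 2.5)))
  expect_equal(within_trial_length_mad(trs), 1)
  expect_true(is.na(within_trial_length_mad(list(sacc_trial(7)))))
})

test_that("the main-sequence fit is exact on power-law data and range-limited", {
  amps <- exp(seq(log(0.15), log(9), length.out = 40))
  sacc <- data.frame(amplitude = amps, peak_velocity = 100 * sqrt(amps))
  fit <- fit_main_sequence(sacc)
  expect_equal(fit$intercept_a, 2, tolerance = 1e-9)
  expect_equal(fit$slope_b, 0.5, tolerance = 1e-9)

  with_out <- rbind(sacc, data.frame(amplitude = c(12, 15, 0.05),
                                     peak_velocity = c(5, 5, 500)))
  fit2 <- fit_main_sequence(with_out)
  expect_equal(fit2$n_saccades, 40)   # out-of-range saccades excluded
  expect_equal(fit2$slope_b, 0.5, tolerance = 1e-9)

  few <- fit_main_sequence(sacc[1:5, ])
  expect_false(few$valid)
  expect_true(is.na(main_sequence_area(few)))
})

test_that("the main-sequence integral matches numeric quadrature", {
  fit <- structure(list(intercept_a = 2, slope_b = 0.5, n_saccades = 40,
                        fit_range = c(0.1, 10), valid = TRUE),
                   class = "main_sequence_fit")
  raw <- main_sequence_area(fit)
  oracle <- stats::integrate(function(A) 2 + 0.5 * log10(A), 0.1, 10,
                             rel.tol = 1e-12)$value
  expect_equal(raw, oracle, tolerance = 1e-9)

  flat <- structure(list(intercept_a = 1.7, slope_b = 0, n_saccades = 40,
                         fit_range = c(0.1, 10), valid = TRUE),
                    class = "main_sequence_fit")
  expect_equal(main_sequence_area(flat), 9.9 * 1.7)
  expect_error(main_sequence_area(fit, lower = 5, upper = 2), "range")

  expect_equal(normalize_ms_area(c(raw, raw)), c(1, 1))
})

test_that("directional statistics are signed and tie-robust", {
  sym <- sacc_trial(c(2, 2), angles = c(0, pi))
  expect_equal(directional_stats(list(sym))$delta_sac, 0)

  trs <- list(sacc_trial(c(3, 3, 2), angles = c(0, 0, pi)))
  d <- directional_stats(trs)
  expect_equal(d$delta_sac, 1)
  expect_equal(d$n_right, 2)

  # purely vertical saccades are ties and excluded from both classes
  vert <- fix_trial(c(0, 0, 0), y = c(0, 2, -1))
  dv <- directional_stats(list(vert))
  expect_equal(dv$n_right + dv$n_left, 0)
  expect_true(is.na(dv$delta_sac))

  only_right <- sacc_trial(2, angles = 0)
  expect_true(is.na(directional_stats(list(only_right))$delta_sac))

  # mirror reflection flips the sign exactly
  flipped <- directional_stats(lapply(trs, mirror_trial))
  expect_equal(flipped$delta_sac, -1)
})

test_that("explored area covers discs and saturates at 100", {
  bounds <- c(28.5, 18)
  one <- explored_area(list(fix_trial(0)), bounds = bounds, radius = 1)
  expect_equal(one, 100 * pi / (28.5 * 18), tolerance = 0.03)

  all_img <- explored_area(list(fix_trial(0)), bounds = bounds, radius = 40)
  expect_equal(all_img, 100)

  outside <- explored_area(list(fix_trial(30)), bounds = bounds)
  expect_equal(outside, 0)
})

test_that("length metrics are invariant under time and space translation", {
  set.seed(61)
  tr <- simulate_trial(scanpath_model(bounds = c(60, 40)))
  shift <- tr
  shift$fixations$t_start <- shift$fixations$t_start + 500
  shift$fixations$t_end <- shift$fixations$t_end + 500
  shift$saccades$t_start <- shift$saccades$t_start + 500
  shift$saccades$t_end <- shift$saccades$t_end + 500
  shift$duration <- shift$duration + 500
  expect_equal(saccade_length_stats(list(shift)),
               saccade_length_stats(list(tr)))
  expect_equal(within_trial_length_mad(list(shift)),
               within_trial_length_mad(list(tr)))

  spat <- tr
  spat$fixations$x <- spat$fixations$x + 2
  spat$saccades$x0 <- spat$saccades$x0 + 2
  spat$saccades$x1 <- spat$saccades$x1 + 2
  expect_equal(saccade_length_stats(list(spat)),
               saccade_length_stats(list(tr)))
})

test_that("the oculomotor summary assembles consistent per-subject rows", {
  m <- scanpath_model(n_trials = 6)
  set.seed(71)
  trs <- lapply(1:6, function(k) simulate_trial(m, subject_id = "P01",
                                                condition = "OFF"))
  row <- oculomotor_summary(trs)
  expect_equal(row$subject_id, "P01")
  expect_gt(row$n_saccades, 50)
  expect_equal(row$n_right + row$n_left, row$n_saccades)
  expect_true(row$explored_area_pct > 0 && row$explored_area_pct < 100)
  expect_equal(row$mean_saccade_length, saccade_length_stats(trs))
  expect_equal(row$ms_area_raw,
               main_sequence_area(fit_main_sequence(trs)))
})
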