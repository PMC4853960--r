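test_that("hdi returns the shortest interval at the requested mass", {
  expect_equal(unname(hdi(rep(3.2, 500))), c(3.2, 3.2))

  set.seed(101)
  u <- runif(1e6)
  iu <- hdi(u, 0.95)
  expect_equal(unname(iu[2] - iu[1]), 0.95, tolerance = 0.005)

  z <- rnorm(1e6)
  iz <- hdi(z, 0.95)
  expect_equal(unname(iz[1]), -1.96, tolerance = 0.02)
  expect_equal(unname(iz[2]), 1.96, tolerance = 0.02)

  # a skewed posterior gets an asymmetric (shortest) interval, unlike
  # equal-tailed quantiles
  g <- rexp(1e5)
  ig <- hdi(g, 0.9)
  expect_lt(ig[1], 0.01)

  expect_error(hdi(rnorm(50)), "100")
  expect_error(hdi(rnorm(500), mass = 1), "mass")
})

test_that("two-group BEST recovers a unit difference and agrees with the
           frequentist mean difference at large n", {
  set.seed(102)
  y1 <- rnorm(400, 1, 1)
  y2 <- rnorm(400, 0, 1)
  ps <- best_two_group(y1, y2, fast_best(seed = 3, draws = 1500))
  est <- ps$estimates
  d <- est[est$parameter == "mu_diff", ]
  expect_equal(d$mean, 1, tolerance = 0.1)
  expect_equal(d$mean, mean(y1) - mean(y2), tolerance = 0.05)
  es <- est[est$parameter == "effect_size", ]
  expect_equal(es$mean, 1, tolerance = 0.15)
  expect_true(hdi_excludes_zero(ps))
  expect_true(all(est$rhat < 1.1))
})

test_that("identical groups yield a difference HDI containing zero", {
  set.seed(103)
  y <- rnorm(30)
  ps <- best_two_group(y, y, fast_best(seed = 4))
  expect_false(hdi_excludes_zero(ps))
  expect_error(best_two_group(1:2, 1:10), "at least 3")
})

test_that("paired BEST is antisymmetric under sign flip and handles nulls", {
  d <- c(0.4, -0.1, 0.5, 0.2, 0.7, -0.3, 0.4, 0.1, 0.6, 0.3)
  p1 <- best_paired(d, fast_best(seed = 5))
  p2 <- best_paired(-d, fast_best(seed = 5))
  m1 <- p1$estimates[p1$estimates$parameter == "mu", ]
  m2 <- p2$estimates[p2$estimates$parameter == "mu", ]
  # the model is sign-equivariant; the sampler trajectories are not mirror
  # images, so agreement is to Monte-Carlo error
  expect_lt(abs(m1$mean + m2$mean), 0.005)
  expect_lt(abs(m1$hdi_low + m2$hdi_high), 0.03)

  # degenerate all-zero differences: posterior collapses onto zero (the
  # normality parameter is unidentified there, so convergence only warns)
  suppressWarnings(
    z <- best_paired(rep(0, 12),
                     fast_best(seed = 6, on_nonconvergence = "warn")))
  mz <- z$estimates[z$estimates$parameter == "mu", ]
  expect_lt(abs(mz$mean), 1e-3)
  expect_lt(mz$hdi_high - mz$hdi_low, 1e-2)
})

test_that("the ANOVA-like model shrinks null contrasts and flags real ones", {
  set.seed(104)
  subj <- rep(sprintf("s%02d", 1:14), each = 4)
  cond <- rep(c("OFF", "ON", "veL", "veR"), 14)
  null_y <- rnorm(56, 3, 0.5)
  pa0 <- bayes_anova_four(null_y, subj, cond, fast_best(seed = 7))
  for (p in grep("_minus_", pa0$estimates$parameter, value = TRUE)) {
    expect_false(hdi_excludes_zero(pa0, p))
  }

  mu <- c(OFF = 2.79, ON = 3.14, veL = 2.95, veR = 2.95)
  sv <- rnorm(14, 0, 0.5)
  y <- mu[cond] + sv[match(subj, unique(subj))] + rnorm(56, 0, 0.1)
  pa <- bayes_anova_four(y, subj, cond, fast_best(seed = 8))
  expect_true(hdi_excludes_zero(pa, "OFF_minus_ON"))
  off_on <- pa$estimates[pa$estimates$parameter == "OFF_minus_ON", ]
  # posterior tracks the realized paired difference (shrunk toward zero)
  d_obs <- mean(y[cond == "OFF"] - y[cond == "ON"])
  expect_lt(abs(off_on$mean - d_obs), 0.1)
  expect_gt(abs(off_on$mean), 0.5 * abs(d_obs))

  # unbalanced missingness: some subjects observed in two conditions only
  keep <- !(subj %in% c("s13", "s14") & cond %in% c("veL", "veR"))
  expect_s3_class(bayes_anova_four(y[keep], subj[keep], cond[keep],
                                   fast_best(seed = 9)),
                  "posterior_summary")
  expect_error(bayes_anova_four(y[cond %in% c("OFF", "ON") | subj == "s01"],
                                subj[cond %in% c("OFF", "ON") | subj == "s01"],
                                cond[cond %in% c("OFF", "ON") | subj == "s01"]),
               "at least 3 observations")
})

test_that("the decision rule is HDI-excludes-zero with a conservative tie", {
  fake <- function(lo, hi) {
    structure(list(estimates = tibble::tibble(
      parameter = "mu_diff", mean = (lo + hi) / 2, hdi_low = lo,
      hdi_high = hi, rhat = 1, ess = 1e4)), class = "posterior_summary")
  }
  expect_true(hdi_excludes_zero(fake(0.06, 0.52)))
  expect_false(hdi_excludes_zero(fake(-0.07, 1.35)))
  expect_false(hdi_excludes_zero(fake(0, 0.5)))     # boundary contains zero
  expect_true(hdi_excludes_zero(fake(-0.5, -0.01)))
  expect_error(hdi_excludes_zero(fake(0, 1), "sigma"), "no such")
})

test_that("seeded MCMC runs are bit-reproducible", {
  d <- c(0.2, 0.5, -0.1, 0.3, 0.8, 0.1, 0.4)
  a <- best_paired(d, fast_best(seed = 11))
  b <- best_paired(d, fast_best(seed = 11))
  expect_identical(a$estimates, b$estimates)
  c2 <- best_paired(d, fast_best(seed = 12))
  expect_false(identical(a$estimates$mean, c2$estimates$mean))
})
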