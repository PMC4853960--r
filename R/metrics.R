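# Pool saccades (or fixations) across a subject's trials into one data frame.
.pool_saccades <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) tr$saccades))
}
.pool_fixations <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) tr$fixations))
}

#' Mean saccade length
#'
#' Arithmetic mean of saccade amplitudes over all trials of one
#' subject-condition. `per_trial = TRUE` averages trial means instead of
#' pooling saccades (both aggregations are defensible; pooled is the
#' default).
#'
#' @param trials List of [trial()] objects (one subject-condition).
#' @param per_trial Average of trial means instead of the pooled mean.
#' @return Mean amplitude in deg, or `NA` if there are no saccades
#'   (undefined, not zero).
#' @export
saccade_length_stats <- function(trials, per_trial = FALSE) {
  if (per_trial) {
    m <- vapply(trials, function(tr) {
      if (nrow(tr$saccades)) mean(tr$saccades$amplitude) else NA_real_
    }, 0)
    if (all(is.na(m))) return(NA_real_)
    return(mean(m, na.rm = TRUE))
  }
  s <- .pool_saccades(trials)
  if (is.null(s) || !nrow(s)) return(NA_real_)
  mean(s$amplitude)
}

#' Within-trial saccade-length variability
#'
#' The unscaled median absolute deviation of saccade amplitudes within each
#' trial — `median(|len - median(len)|)`, with no 1.4826 consistency factor —
#' aggregated to the subject level as the median over trials. Trials with
#' fewer than two saccades are skipped.
#'
#' @inheritParams saccade_length_stats
#' @return Median trialwise MAD in deg, `NA` if every trial was skipped.
#' @export
within_trial_length_mad <- function(trials) {
  mads <- vapply(trials, function(tr) {
    len <- tr$saccades$amplitude
    if (length(len) < 2) return(NA_real_)
    stats::median(abs(len - stats::median(len)))
  }, 0)
  if (all(is.na(mads))) return(NA_real_)
  stats::median(mads, na.rm = TRUE)
}

#' Fit the saccadic main sequence
#'
#' Ordinary least squares of `log10(peak_velocity)` on `log10(amplitude)`,
#' restricted to amplitudes in `fit_range` where the log-log relation is
#' linear. At least 10 in-range saccades are required for a valid fit.
#'
#' @inheritParams saccade_length_stats
#' @param fit_range Amplitude range in deg used for the fit
#'   (default `c(0.1, 10)`).
#' @return An object of class `main_sequence_fit` with `intercept_a`
#'   (log10 deg/s at 1 deg), `slope_b`, `n_saccades`, `fit_range`; or an
#'   invalid-fit marker (`valid = FALSE`) when too few saccades are in range.
#' @export
fit_main_sequence <- function(trials, fit_range = c(0.1, 10)) {
  s <- if (is.data.frame(trials)) trials else .pool_saccades(trials)
  s <- s[!is.na(s$peak_velocity) & s$amplitude >= fit_range[1] &
           s$amplitude <= fit_range[2], , drop = FALSE]
  if (is.null(s) || nrow(s) < 10) {
    return(structure(list(intercept_a = NA_real_, slope_b = NA_real_,
                          n_saccades = if (is.null(s)) 0L else nrow(s),
                          fit_range = fit_range, valid = FALSE),
                     class = "main_sequence_fit"))
  }
  fit <- stats::lm(log10(peak_velocity) ~ log10(amplitude), data = s)
  structure(list(intercept_a = unname(stats::coef(fit)[1]),
                 slope_b = unname(stats::coef(fit)[2]),
                 n_saccades = nrow(s), fit_range = fit_range, valid = TRUE),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  if (!x$valid) {
    cat("<main_sequence_fit> invalid (", x$n_saccades, "in-range saccades)\n")
  } else {
    cat(sprintf("<main_sequence_fit> log10(v) = %.3f + %.3f log10(A), n = %d in [%g, %g] deg\n",
                x$intercept_a, x$slope_b, x$n_saccades,
                x$fit_range[1], x$fit_range[2]))
  }
  invisible(x)
}

#' Definite integral of the main sequence
#'
#' Closed-form integral of the fitted log-velocity over amplitude,
#' `int_l^u (a + b log10 A) dA = a (u - l) + b [A (ln A - 1)] / ln 10` between
#' the limits — a single length-controlled summary of saccadic vigour that is
#' insensitive to the amplitude distribution. The raw value carries units of
#' deg x log10(deg/s); [normalize_ms_area()] rescales a cohort of raw values
#' by their grand mean so the cohort averages to 1.
#'
#' @param fit A valid [fit_main_sequence()] result.
#' @param lower,upper Integration limits in deg (default 0.1 and 10).
#' @return The raw integral value.
#' @export
main_sequence_area <- function(fit, lower = 0.1, upper = 10) {
  stopifnot(inherits(fit, "main_sequence_fit"))
  if (!isTRUE(fit$valid)) return(NA_real_)
  if (upper <= lower) stop("invalid range: upper must exceed lower",
                           call. = FALSE)
  prim <- function(A) A * (log(A) - 1) / log(10)
  fit$intercept_a * (upper - lower) + fit$slope_b * (prim(upper) - prim(lower))
}

#' Cohort-normalized main-sequence areas
#'
#' @param raw Numeric vector of raw [main_sequence_area()] values, one per
#'   subject.
#' @return `raw / mean(raw)` (missing values excluded from the grand mean).
#' @export
normalize_ms_area <- function(raw) {
  raw / mean(raw, na.rm = TRUE)
}

#' Left/right directional saccade statistics
#'
#' Counts and mean lengths of leftward and rightward saccades (direction
#' classified by the sign of the horizontal displacement; exact ties are
#' excluded from both classes), and their difference
#' `delta_sac = mean rightward - mean leftward length` (positive = rightward
#' saccades longer).
#'
#' @inheritParams saccade_length_stats
#' @return A list with `n_right`, `n_left`, `mean_right`, `mean_left`,
#'   `count_ratio` (right / left) and `delta_sac` (`NA` when a class is
#'   empty).
#' @export
directional_stats <- function(trials) {
  s <- .pool_saccades(trials)
  out <- list(n_right = 0L, n_left = 0L, mean_right = NA_real_,
              mean_left = NA_real_, count_ratio = NA_real_,
              delta_sac = NA_real_)
  if (is.null(s) || !nrow(s)) return(out)
  s <- s[!is.na(s$direction), , drop = FALSE]
  r <- s$amplitude[s$direction == "rightward"]
  l <- s$amplitude[s$direction == "leftward"]
  out$n_right <- length(r); out$n_left <- length(l)
  if (length(r)) out$mean_right <- mean(r)
  if (length(l)) out$mean_left <- mean(l)
  if (length(l)) out$count_ratio <- length(r) / length(l)
  if (length(r) && length(l)) out$delta_sac <- mean(r) - mean(l)
  out
}

#' Explored image area
#'
#' Fraction of the image covered by the union of discs of radius `radius`
#' around the trial's fixations, evaluated on a `cell`-spaced grid, per trial;
#' the subject value is the median over trials. The 1-deg default radius
#' approximates the foveal extent.
#'
#' @inheritParams saccade_length_stats
#' @param bounds Image extent `c(width_deg, height_deg)`.
#' @param radius Disc radius in deg.
#' @param cell Grid spacing in deg.
#' @return Percentage of the image explored (0-100), median over trials.
#' @export
explored_area <- function(trials, bounds = c(43.4, 27.9), radius = 1,
                          cell = 0.1) {
  gx <- seq(-bounds[1] / 2 + cell / 2, bounds[1] / 2 - cell / 2, by = cell)
  gy <- seq(-bounds[2] / 2 + cell / 2, bounds[2] / 2 - cell / 2, by = cell)
  per_trial <- vapply(trials, function(tr) {
    f <- tr$fixations
    f <- f[abs(f$x) <= bounds[1] / 2 & abs(f$y) <= bounds[2] / 2, ,
           drop = FALSE]
    if (!nrow(f)) return(0)
    covered <- matrix(FALSE, length(gy), length(gx))
    for (k in seq_len(nrow(f))) {
      # only the disc's bounding box can be covered
      ix <- which(abs(gx - f$x[k]) <= radius)
      iy <- which(abs(gy - f$y[k]) <= radius)
      if (!length(ix) || !length(iy)) next
      hit <- outer((gy[iy] - f$y[k])^2, (gx[ix] - f$x[k])^2, "+") <= radius^2
      covered[iy, ix] <- covered[iy, ix] | hit
    }
    100 * mean(covered)
  }, 0)
  stats::median(per_trial)
}

# circular MAD of saccade directions (radians): median absolute wrapped
# deviation from the circular mean direction
.circular_mad <- function(angles) {
  if (!length(angles)) return(NA_real_)
  m <- atan2(mean(sin(angles)), mean(cos(angles)))
  d <- angles - m
  d <- atan2(sin(d), cos(d))
  stats::median(abs(d))
}

#' Per-subject oculomotor summary
#'
#' Assembles the oculomotor metrics of one subject-condition into a single
#' row: mean saccade length, within-trial length MAD, main-sequence fit and
#' raw area, saccade count, explored area, mean fixation duration, circular
#' MAD of saccade angles, and the left/right statistics. The circular-MAD
#' reading of "saccade angle variability" is an implementation assumption.
#'
#' @inheritParams explored_area
#' @param fit_range Main-sequence fit range, deg.
#' @return A one-row tibble.
#' @export
oculomotor_summary <- function(trials, bounds = c(43.4, 27.9),
                               fit_range = c(0.1, 10)) {
  s <- .pool_saccades(trials)
  f <- .pool_fixations(trials)
  fit <- fit_main_sequence(trials, fit_range)
  dir <- directional_stats(trials)
  ang <- if (!is.null(s) && nrow(s)) {
    .circular_mad(atan2(s$y1 - s$y0, s$x1 - s$x0))
  } else NA_real_
  tibble::tibble(
    subject_id = trials[[1]]$subject_id,
    condition = trials[[1]]$condition,
    mean_saccade_length = saccade_length_stats(trials),
    length_mad = within_trial_length_mad(trials),
    ms_intercept = fit$intercept_a, ms_slope = fit$slope_b,
    ms_area_raw = main_sequence_area(fit),
    n_saccades = if (is.null(s)) 0L else nrow(s),
    explored_area_pct = explored_area(trials, bounds),
    mean_fixation_duration = if (is.null(f) || !nrow(f)) NA_real_ else
      mean(f$duration),
    angle_mad = ang,
    n_right = dir$n_right, n_left = dir$n_left,
    delta_sac = dir$delta_sac)
}
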