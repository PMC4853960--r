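#' Detection thresholds
#'
#' Velocity/acceleration criteria for saccade parsing. Defaults follow the
#' values published for the standard video-oculography parser (30 deg/s,
#' 8000 deg/s^2); they are configuration, not constants, because the events
#' any downstream metric sees depend on them.
#'
#' @param velocity_threshold Speed above which samples are saccadic, deg/s.
#' @param acceleration_threshold Acceleration criterion, deg/s^2 (a sample is
#'   saccadic if either criterion fires).
#' @param min_saccade_duration Minimum saccade duration, ms.
#' @param min_fixation_duration Minimum fixation duration, ms.
#' @param merge_distance Fixations separated only by a blink are merged when
#'   their centroids are closer than this, deg.
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(velocity_threshold = 30,
                          acceleration_threshold = 8000,
                          min_saccade_duration = 6,
                          min_fixation_duration = 50,
                          merge_distance = 0.5) {
  structure(list(velocity_threshold = velocity_threshold,
                 acceleration_threshold = acceleration_threshold,
                 min_saccade_duration = min_saccade_duration,
                 min_fixation_duration = min_fixation_duration,
                 merge_distance = merge_distance),
            class = "detect_config")
}

# centred moving average (noise suppression before differentiation);
# edges keep the raw value
.smooth_ma <- function(p, k = 5) {
  n <- length(p)
  if (n < k) return(p)
  sm <- as.numeric(stats::filter(p, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- p[is.na(sm)]
  sm
}

# smoothed central difference over a 5-sample window (deg/s); NA at edges
.velocity_5pt <- function(p, dt_ms) {
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt_ms / 1000)
  }
  v
}

#' Detect fixations and saccades in a gaze-sample stream
#'
#' Velocity-based parsing: sample speeds come from a smoothed central
#' difference over a 5-sample window; runs where the speed exceeds the
#' velocity threshold (or the absolute acceleration exceeds the acceleration
#' threshold) and that last at least the minimum saccade duration become
#' saccades, the gaps between them become fixations. Invalid samples
#' (blinks) are excised: each valid segment is parsed separately and
#' fixations that flank a blink are merged when their centroids agree within
#' `merge_distance`. Events truncated by the trial boundary are kept if they
#' reach the applicable minimum duration.
#'
#' @param samples Tibble from [render_samples()] or an equivalent sample
#'   table with columns `t` (ms), `x`, `y` (deg), `valid`.
#' @param geom A [screen_geometry()] (supplies the sampling rate).
#' @param cfg A [detect_config()].
#' @return A list with data frames `fixations` (`t_start`, `t_end`, `x`, `y`,
#'   `duration`) and `saccades` (`t_start`, `t_end`, `x0`, `y0`, `x1`, `y1`,
#'   `amplitude`, `peak_velocity`).
#' @export
detect_events <- function(samples, geom, cfg = detect_config()) {
  stopifnot(inherits(geom, "screen_geometry"))
  dt <- 1000 / geom$sampling_rate_hz
  ok <- samples$valid & is.finite(samples$x) & is.finite(samples$y)
  if (sum(ok) * dt < 100) {
    stop("no data: fewer than 100 ms of valid samples", call. = FALSE)
  }
  # split into maximal valid segments
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg_idx <- Map(seq, starts[r$values], ends[r$values])

  fixations <- list(); saccades <- list()
  for (idx in seg_idx) {
    if (length(idx) < 5) next
    t <- samples$t[idx]
    # noise suppression before differentiation; metrics use smoothed positions
    x <- .smooth_ma(samples$x[idx]); y <- .smooth_ma(samples$y[idx])
    vx <- .velocity_5pt(x, dt); vy <- .velocity_5pt(y, dt)
    sp <- sqrt(vx^2 + vy^2)
    acc <- c(NA, diff(sp)) / (dt / 1000)
    sacc <- (sp > cfg$velocity_threshold) |
      (!is.na(acc) & abs(acc) > cfg$acceleration_threshold &
         sp > cfg$velocity_threshold / 2)
    sacc[is.na(sacc)] <- FALSE
    # grow each saccadic run outward to the onset/offset (speed falling below
    # 30% of the velocity threshold), recovering displacement the threshold
    # crossing misses
    rr <- rle(sacc)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1
    low <- 0.3 * cfg$velocity_threshold
    above_low <- !is.na(sp) & sp > low
    for (k in which(rr$values)) {
      i0 <- rs[k]
      while (i0 > 1 && above_low[i0 - 1]) i0 <- i0 - 1
      i1 <- re[k]
      while (i1 < length(sacc) && above_low[i1 + 1]) i1 <- i1 + 1
      sacc[i0:i1] <- TRUE
    }
    rr <- rle(sacc)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1
    for (k in seq_along(rr$values)) {
      i0 <- rs[k]; i1 <- re[k]
      dur <- t[i1] - t[i0] + dt
      sl <- i0:i1
      if (rr$values[k]) {
        if (dur < cfg$min_saccade_duration) next
        saccades[[length(saccades) + 1]] <- data.frame(
          t_start = t[i0], t_end = t[i1] + dt,
          x0 = x[i0], y0 = y[i0], x1 = x[i1], y1 = y[i1],
          peak_velocity = max(sp[sl], na.rm = TRUE))
      } else {
        if (dur < cfg$min_fixation_duration) next
        fixations[[length(fixations) + 1]] <- data.frame(
          t_start = t[i0], t_end = t[i1] + dt,
          x = mean(x[sl]), y = mean(y[sl]))
      }
    }
  }
  fixations <- if (length(fixations)) do.call(rbind, fixations) else
    data.frame(t_start = numeric(0), t_end = numeric(0),
               x = numeric(0), y = numeric(0))
  saccades <- if (length(saccades)) do.call(rbind, saccades) else
    data.frame(t_start = numeric(0), t_end = numeric(0),
               x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0), peak_velocity = numeric(0))
  fixations <- fixations[order(fixations$t_start), , drop = FALSE]
  saccades <- saccades[order(saccades$t_start), , drop = FALSE]

  # merge fixation pairs separated only by excised samples (blink pseudo-split)
  if (nrow(fixations) > 1) {
    keep <- rep(TRUE, nrow(fixations))
    for (k in 2:nrow(fixations)) {
      prev <- max(which(keep[1:(k - 1)]))
      gap_has_saccade <- any(saccades$t_start >= fixations$t_end[prev] - dt &
                               saccades$t_end <= fixations$t_start[k] + dt)
      d <- sqrt((fixations$x[k] - fixations$x[prev])^2 +
                  (fixations$y[k] - fixations$y[prev])^2)
      if (!gap_has_saccade && d < cfg$merge_distance) {
        w1 <- fixations$t_end[prev] - fixations$t_start[prev]
        w2 <- fixations$t_end[k] - fixations$t_start[k]
        fixations$x[prev] <- (w1 * fixations$x[prev] + w2 * fixations$x[k]) /
          (w1 + w2)
        fixations$y[prev] <- (w1 * fixations$y[prev] + w2 * fixations$y[k]) /
          (w1 + w2)
        fixations$t_end[prev] <- fixations$t_end[k]
        keep[k] <- FALSE
      }
    }
    fixations <- fixations[keep, , drop = FALSE]
  }
  fixations$duration <- fixations$t_end - fixations$t_start
  if (nrow(saccades)) {
    saccades$amplitude <- sqrt((saccades$x1 - saccades$x0)^2 +
                                 (saccades$y1 - saccades$y0)^2)
  } else saccades$amplitude <- numeric(0)
  rownames(fixations) <- NULL; rownames(saccades) <- NULL
  list(fixations = fixations, saccades = saccades)
}

#' Detect events and assemble a trial
#'
#' Convenience wrapper around [detect_events()] returning a validated
#' [trial()].
#'
#' @inheritParams detect_events
#' @param subject_id,condition,image_id,duration Trial metadata.
#' @export
detect_trial <- function(samples, geom, cfg = detect_config(),
                         subject_id = "sub", condition = "OFF",
                         image_id = "img", duration = NULL) {
  ev <- detect_events(samples, geom, cfg)
  if (is.null(duration)) duration <- max(samples$t) + 1000 / geom$sampling_rate_hz
  trial(subject_id, condition, image_id, ev$fixations,
        ev$saccades[, c("t_start", "t_end", "x0", "y0", "x1", "y1",
                        "peak_velocity")],
        duration = duration)
}

#' Data-quality report over trials
#'
#' Event counts, blink fraction and spatial dispersion per trial, with a flag
#' for trials too sparse for the bias measures (fewer than two fixations).
#'
#' @param trials List of [trial()] objects.
#' @param blink_fractions Optional numeric vector (one per trial) of the
#'   fraction of invalid samples, when known from the sample stream.
#' @return A tibble with one row per trial (`n_fixations`, `n_saccades`,
#'   `blink_fraction`, `dispersion`, `flagged`).
#' @export
event_quality_report <- function(trials, blink_fractions = NULL) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    tibble::tibble(
      subject_id = tr$subject_id, condition = tr$condition,
      image_id = tr$image_id,
      n_fixations = nrow(tr$fixations), n_saccades = nrow(tr$saccades),
      blink_fraction = if (is.null(blink_fractions)) NA_real_ else
        blink_fractions[i],
      dispersion = if (nrow(tr$fixations) > 1)
        stats::sd(tr$fixations$x) + stats::sd(tr$fixations$y) else NA_real_,
      flagged = nrow(tr$fixations) < 2)
  })
  do.call(rbind, rows)
}
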