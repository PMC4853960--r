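#' Parameterise a synthetic scanpath generator
#'
#' Defines the statistical structure of simulated 8-s free-viewing trials:
#' log-normal fixation-duration and saccade-amplitude laws, a stationary
#' horizontal shift of the fixation-target distribution (the exploration
#' bias), a separate first-fixation bias, and a power-law main sequence for
#' peak velocities. The defaults describe a healthy control subject viewing a
#' full-screen image on the default [screen_geometry()]; group or condition
#' differences are expressed by overriding `amplitude_mean`,
#' `horizontal_bias` and `first_fixation_bias` (see [cohort_spec()]).
#'
#' The amplitude law is log-normal with `meanlog` chosen so the law's mean is
#' `amplitude_mean`; `amplitude_sdlog` controls the within-trial spread
#' (median absolute deviation) and `amplitude_trial_sdlog` adds a per-trial
#' log-normal scale multiplier with mean 1, so trials differ in their overall
#' amplitude scale. Fixation targets follow a random walk whose candidate
#' directions are drawn uniformly and re-weighted by a centre-seeking
#' attractor (Laplace weights with length scales `pull_scale`) — the soft
#' inward pull that keeps scanpaths on the image without reflection
#' artifacts. The horizontal bias is a rigid stationary shift of that
#' (symmetric) fixation distribution by `horizontal_bias`, not a lengthening
#' of rightward saccades, so the amplitude law and the left/right saccade
#' statistics stay symmetric — matching the empirical dissociation between
#' exploration bias and directional saccade metrics.
#'
#' @param n_trials Trials (image presentations) per subject-condition
#'   (default 35).
#' @param trial_duration Trial length in ms (default 8000).
#' @param fixation_duration_mean,fixation_duration_sdlog Mean (ms) and log-sd
#'   of the log-normal fixation-duration law. Defaults target about three
#'   fixations per second.
#' @param amplitude_mean Mean saccade amplitude in deg.
#' @param amplitude_sdlog Log-sd of the amplitude law.
#' @param amplitude_trial_sdlog Log-sd of the per-trial scale multiplier.
#' @param horizontal_bias Stationary horizontal shift of the fixation-target
#'   distribution, deg (positive = rightward).
#' @param first_fixation_bias Mean horizontal position of the first
#'   (exploratory) fixation, deg.
#' @param first_fixation_sd Trial-to-trial scatter of the first fixation, deg.
#' @param ms_v1 Main-sequence peak velocity at 1 deg amplitude, deg/s.
#' @param ms_exponent Main-sequence power-law exponent.
#' @param ms_sdlog Log-normal noise of peak velocity around the power law.
#' @param bounds Image extent `c(width_deg, height_deg)`; fixations stay
#'   inside. Defaults to the full default screen.
#' @param pull_scale Length scales `c(x, y)` in deg of the centre-seeking
#'   attractor controlling the stationary fixation spread.
#'
#' @return An object of class `scanpath_model`.
#' @seealso [simulate_trial()], [simulate_cohort()]
#' @export
scanpath_model <- function(n_trials = 35, trial_duration = 8000,
                           fixation_duration_mean = 280,
                           fixation_duration_sdlog = 0.4,
                           amplitude_mean = 3.79, amplitude_sdlog = 0.75,
                           amplitude_trial_sdlog = 0.15,
                           horizontal_bias = 0, first_fixation_bias = -1,
                           first_fixation_sd = 2,
                           ms_v1 = 70, ms_exponent = 0.6, ms_sdlog = 0.1,
                           bounds = c(43.4, 27.9), pull_scale = c(6, 4)) {
  scales <- c(fixation_duration_mean, fixation_duration_sdlog,
              amplitude_mean, amplitude_sdlog, amplitude_trial_sdlog,
              first_fixation_sd, ms_v1, ms_exponent, ms_sdlog,
              bounds, pull_scale)
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("all scale parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (any(bounds < 2 * amplitude_mean)) {
    stop("infeasible model: image bounds smaller than twice the amplitude scale",
         call. = FALSE)
  }
  m <- list(n_trials = n_trials, trial_duration = trial_duration,
            fixation_duration_mean = fixation_duration_mean,
            fixation_duration_sdlog = fixation_duration_sdlog,
            amplitude_mean = amplitude_mean, amplitude_sdlog = amplitude_sdlog,
            amplitude_trial_sdlog = amplitude_trial_sdlog,
            horizontal_bias = horizontal_bias,
            first_fixation_bias = first_fixation_bias,
            first_fixation_sd = first_fixation_sd,
            ms_v1 = ms_v1, ms_exponent = ms_exponent, ms_sdlog = ms_sdlog,
            bounds = bounds, pull_scale = pull_scale)
  structure(m, class = "scanpath_model")
}

# lognormal meanlog for a target mean at given sdlog
.lnorm_meanlog <- function(mean, sdlog) log(mean) - sdlog^2 / 2

.clip_to_bounds <- function(p, bounds, margin = 0.1) {
  half <- bounds / 2 - margin
  pmin(pmax(p, -half), half)
}

#' Simulate one free-viewing trial
#'
#' Generates an alternating fixation/saccade sequence filling the trial. The
#' first fixation lands at the model's first-fixation bias plus Gaussian
#' scatter; each later fixation target is drawn by sampling an amplitude from
#' the amplitude law and choosing among uniformly drawn directions with
#' centre-seeking attractor weights (zero outside the image), so amplitudes
#' follow the configured law while scanpaths stay on the image. The whole
#' fixation process is then rigidly shifted by `horizontal_bias` (the chain
#' runs in bias-centred coordinates against correspondingly shifted bounds),
#' giving a stationary rightward/leftward exploration shift without any
#' left/right asymmetry in the saccades themselves. Saccade peak velocity
#' follows the main sequence with multiplicative log-normal noise, and the
#' saccade duration is the one a raised-cosine velocity profile needs to
#' cover the amplitude at that peak velocity. Events never extend past
#' `trial_duration`.
#'
#' Uses the current R random number stream; seed with `set.seed()` (or pass
#' `seed`) for reproducibility.
#'
#' @param model A [scanpath_model()].
#' @param subject_id,condition,image_id Labels for the returned [trial()].
#' @param seed Optional integer seed applied before generation.
#' @return A validated [trial()] object.
#' @export
simulate_trial <- function(model, subject_id = "sim", condition = "CTRL1",
                           image_id = "img1", seed = NULL) {
  stopifnot(inherits(model, "scanpath_model"))
  if (!is.null(seed)) set.seed(seed)
  half <- model$bounds / 2
  mu_a <- .lnorm_meanlog(model$amplitude_mean, model$amplitude_sdlog)
  mu_d <- .lnorm_meanlog(model$fixation_duration_mean,
                         model$fixation_duration_sdlog)
  trial_scale <- stats::rlnorm(1, -model$amplitude_trial_sdlog^2 / 2,
                               model$amplitude_trial_sdlog)
  b <- model$horizontal_bias
  # the chain runs in bias-centred coordinates: attractor at 0, image window
  # shifted by -b; positions are shifted back (+b) when events are emitted
  first_abs <- .clip_to_bounds(
    c(model$first_fixation_bias, 0) +
      stats::rnorm(2, 0, model$first_fixation_sd),
    model$bounds)
  pos <- first_abs - c(b, 0)
  t <- 0
  fx <- list(); sc <- list()
  repeat {
    dur <- stats::rlnorm(1, mu_d, model$fixation_duration_sdlog)
    t_end <- min(t + dur, model$trial_duration)
    fx[[length(fx) + 1]] <- c(t, t_end, pos + c(b, 0))
    t <- t_end
    if (t >= model$trial_duration) break
    # saccade target: amplitude from the law, direction by attractor weights
    amp <- trial_scale * stats::rlnorm(1, mu_a, model$amplitude_sdlog)
    target <- NULL
    for (try in 1:8) {
      theta <- stats::runif(40, 0, 2 * pi)
      cand_x <- pos[1] + amp * cos(theta)
      cand_y <- pos[2] + amp * sin(theta)
      inb <- abs(cand_x + b) < half[1] & abs(cand_y) < half[2]
      if (any(inb)) {
        w <- ifelse(inb,
                    exp(-(abs(cand_x) / model$pull_scale[1] +
                            abs(cand_y) / model$pull_scale[2])),
                    0)
        j <- sample.int(40, 1, prob = w)
        target <- c(cand_x[j], cand_y[j])
        break
      }
      amp <- amp / 2  # too large to land anywhere on the image from here
    }
    if (is.null(target)) target <- c(-b, 0)
    amp_real <- sqrt(sum((target - pos)^2))
    if (amp_real < 1e-6) next
    vp <- model$ms_v1 * amp_real^model$ms_exponent *
      stats::rlnorm(1, 0, model$ms_sdlog)
    sdur <- 2000 * amp_real / vp  # raised-cosine profile: D = 2A / v_peak
    if (t + sdur >= model$trial_duration) break
    sc[[length(sc) + 1]] <- c(t, t + sdur, pos + c(b, 0), target + c(b, 0), vp)
    t <- t + sdur
    pos <- target
  }
  fx <- do.call(rbind, fx)
  fixations <- data.frame(t_start = fx[, 1], t_end = fx[, 2],
                          x = fx[, 3], y = fx[, 4])
  if (length(sc)) {
    sc <- do.call(rbind, sc)
    saccades <- data.frame(t_start = sc[, 1], t_end = sc[, 2],
                           x0 = sc[, 3], y0 = sc[, 4],
                           x1 = sc[, 5], y1 = sc[, 6],
                           peak_velocity = sc[, 7])
  } else {
    saccades <- data.frame(t_start = numeric(0), t_end = numeric(0),
                           x0 = numeric(0), y0 = numeric(0),
                           x1 = numeric(0), y1 = numeric(0),
                           peak_velocity = numeric(0))
  }
  trial(subject_id, condition, image_id, fixations, saccades,
        duration = model$trial_duration)
}

#' Specify a simulated cohort
#'
#' Describes a patient/control cohort: group sizes, the per-condition
#' generator parameters (mean saccade amplitude, horizontal exploration bias
#' and first-fixation bias), and the between-subject and between-condition
#' variability around them. The defaults emulate the structure of a 17/17
#' STN-DBS free-viewing cohort: saccadic hypometria in the unstimulated state
#' (mean amplitude 2.79 deg vs 3.79 deg in controls, partly restored to 3.14
#' deg by bilateral stimulation, intermediate under unilateral stimulation), a
#' rightward exploration bias in patients, a leftward first-fixation bias in
#' controls that is absent in patients, and three patients recorded in only
#' the OFF and ON conditions.
#'
#' @param n_patients,n_controls Group sizes (default 17 each).
#' @param n_two_condition Number of patients recorded only in OFF and ON
#'   (default 3).
#' @param condition_params Data frame with columns `condition`,
#'   `amplitude_mean`, `horizontal_bias`, `first_fixation_bias`; one row per
#'   condition to simulate. Defaults cover OFF/ON/veL/veR and the two control
#'   runs.
#' @param between_sd Named numeric: between-subject SDs of `amplitude`,
#'   `bias` and `first_fix`.
#' @param within_sd Named numeric: condition-to-condition (within-subject)
#'   SDs of the same parameters.
#' @param base_model A [scanpath_model()] supplying all remaining parameters.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 17, n_controls = 17,
                        n_two_condition = 3,
                        condition_params = NULL,
                        between_sd = c(amplitude = 0.69, bias = 1.0,
                                       first_fix = 1.3),
                        within_sd = c(amplitude = 0.55, bias = 0.3,
                                      first_fix = 0.3),
                        base_model = scanpath_model()) {
  if (is.null(condition_params)) {
    condition_params <- data.frame(
      condition = c("OFF", "ON", "veL", "veR", "CTRL1", "CTRL2"),
      amplitude_mean = c(2.79, 3.14, 2.95, 2.95, 3.79, 3.79),
      horizontal_bias = c(0.89, 0.77, 0.95, 0.48, 0, 0),
      first_fixation_bias = c(0.14, 0.14, 0.14, 0.14, -1, -1))
  }
  bad <- setdiff(condition_params$condition, dbs_conditions())
  if (length(bad)) {
    stop("unknown condition in condition_params: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_two_condition > n_patients) {
    stop("n_two_condition cannot exceed n_patients", call. = FALSE)
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_two_condition = n_two_condition,
                 condition_params = condition_params,
                 between_sd = between_sd, within_sd = within_sd,
                 base_model = base_model),
            class = "cohort_spec")
}

#' Simulate a full cohort of free-viewing recordings
#'
#' Draws per-subject parameter offsets around the group means of the
#' [cohort_spec()], then per-condition values with within-subject jitter, and
#' simulates all trials. All randomness flows from `seed`: each
#' subject-condition cell gets an independent derived stream, so the same
#' seed reproduces the cohort bit-identically.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A tibble with one row per subject-condition: `subject_id`, `group`
#'   (`"patient"`/`"control"`), `condition`, `trials` (list-column of
#'   [trial()] objects) plus the realised generator parameters
#'   (`amplitude_mean`, `horizontal_bias`, `first_fixation_bias`).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  cp <- spec$condition_params
  pat_conds <- intersect(c("OFF", "ON", "veL", "veR"), cp$condition)
  ctl_conds <- intersect(c("CTRL1", "CTRL2"), cp$condition)
  subjects <- rbind(
    if (spec$n_patients > 0)
      data.frame(subject_id = sprintf("P%02d", seq_len(spec$n_patients)),
                 group = "patient"),
    if (spec$n_controls > 0)
      data.frame(subject_id = sprintf("C%02d", seq_len(spec$n_controls)),
                 group = "control"))
  if (is.null(subjects)) {
    return(tibble::tibble(subject_id = character(0), group = character(0),
                          condition = character(0), trials = list(),
                          amplitude_mean = numeric(0),
                          horizontal_bias = numeric(0),
                          first_fixation_bias = numeric(0)))
  }
  set.seed(seed)
  # independent per-cell RNG substreams derived from the master seed
  cell_seed <- function(i, j) (seed + 10007L * i + 211L * j) %% 2147483647L
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    set.seed(cell_seed(i, 0L))
    off <- c(amplitude = stats::rnorm(1, 0, spec$between_sd[["amplitude"]]),
             bias = stats::rnorm(1, 0, spec$between_sd[["bias"]]),
             first_fix = stats::rnorm(1, 0, spec$between_sd[["first_fix"]]))
    conds <- if (grp == "patient") pat_conds else ctl_conds
    if (grp == "patient" &&
        i > spec$n_patients - spec$n_two_condition) {
      conds <- intersect(conds, c("OFF", "ON"))
    }
    for (j in seq_along(conds)) {
      cnd <- conds[j]
      p <- cp[cp$condition == cnd, ]
      set.seed(cell_seed(i, match(cnd, dbs_conditions())))
      amp <- max(0.8, p$amplitude_mean + off[["amplitude"]] +
                   stats::rnorm(1, 0, spec$within_sd[["amplitude"]]))
      hb <- p$horizontal_bias + off[["bias"]] +
        stats::rnorm(1, 0, spec$within_sd[["bias"]])
      ffb <- p$first_fixation_bias + off[["first_fix"]] +
        stats::rnorm(1, 0, spec$within_sd[["first_fix"]])
      model <- spec$base_model
      model$amplitude_mean <- amp
      model$horizontal_bias <- hb
      model$first_fixation_bias <- ffb
      trials <- lapply(seq_len(model$n_trials), function(k) {
        simulate_trial(model, subject_id = sid, condition = cnd,
                       image_id = sprintf("img%02d", k))
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, group = grp, condition = cnd,
        trials = list(trials), amplitude_mean = amp, horizontal_bias = hb,
        first_fixation_bias = ffb)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Render gaze samples from a trial's events
#'
#' Produces a raw sample stream at the geometry's sampling rate: fixation
#' samples are the fixation position plus isotropic Gaussian noise; saccade
#' samples follow a straight path with a raised-cosine speed profile whose
#' peak equals the event's `peak_velocity` and whose time integral equals its
#' amplitude. Samples inside `blink_windows` are marked invalid and carry no
#' position, emulating blinks.
#'
#' @param tr A [trial()].
#' @param geom A [screen_geometry()] (supplies the sampling rate).
#' @param noise_sd Fixation sample noise SD in deg (>= 0).
#' @param blink_windows Optional data frame with `t_start`, `t_end` (ms) of
#'   invalid stretches.
#' @return A tibble with columns `t` (ms), `x`, `y` (deg) and `valid`.
#' @export
render_samples <- function(tr, geom, noise_sd = 0.05, blink_windows = NULL) {
  stopifnot(inherits(tr, "trial"), inherits(geom, "screen_geometry"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  rate <- geom$sampling_rate_hz
  if (rate <= 0) stop("invalid sampling rate", call. = FALSE)
  dt <- 1000 / rate
  t <- seq(0, tr$duration - dt, by = dt)
  x <- numeric(length(t)); y <- numeric(length(t))
  # default: hold the nearest fixation position
  f <- tr$fixations
  idx <- findInterval(t, f$t_start)
  idx[idx == 0] <- 1
  x <- f$x[idx]; y <- f$y[idx]
  if (noise_sd > 0) {
    infix <- t >= f$t_start[idx] & t < f$t_end[idx]
    x[infix] <- x[infix] + stats::rnorm(sum(infix), 0, noise_sd)
    y[infix] <- y[infix] + stats::rnorm(sum(infix), 0, noise_sd)
  }
  s <- tr$saccades
  for (k in seq_len(nrow(s))) {
    sel <- t >= s$t_start[k] & t < s$t_end[k]
    if (!any(sel)) next
    D <- s$t_end[k] - s$t_start[k]
    u <- (t[sel] - s$t_start[k]) / D
    # displacement fraction of the raised-cosine profile
    frac <- u - sin(2 * pi * u) / (2 * pi)
    x[sel] <- s$x0[k] + frac * (s$x1[k] - s$x0[k])
    y[sel] <- s$y0[k] + frac * (s$y1[k] - s$y0[k])
  }
  valid <- rep(TRUE, length(t))
  if (!is.null(blink_windows)) {
    for (k in seq_len(nrow(blink_windows))) {
      sel <- t >= blink_windows$t_start[k] & t < blink_windows$t_end[k]
      valid[sel] <- FALSE
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
  }
  tibble::tibble(t = t, x = x, y = y, valid = valid)
}

#' Simulate an electrode cohort with a linear bias gradient
#'
#' Scatters stimulation sites around the left-sided centroid of the packaged
#' electrode table and assigns each site a bias equal to a linear gradient
#' along `direction` plus Gaussian noise — the generative model under which
#' the electrode-position regression is exactly identified.
#'
#' @param n Number of sites (>= 5; the regression needs residual df).
#' @param direction Unit 3-vector along which bias changes.
#' @param gradient Bias change per mm along `direction`.
#' @param noise_sd SD of additive bias noise.
#' @param seed Optional seed.
#' @param centroid,scatter_sd Optional centre and per-axis SD of the site
#'   cloud; default to the packaged left-side values.
#' @return A tibble shaped like [load_electrode_sites()] (left side only)
#'   with the simulated `init_bias`.
#' @export
simulate_electrode_cohort <- function(n = 14, direction = c(0, 1, 0),
                                      gradient = 0.5, noise_sd = 0.5,
                                      seed = NULL, centroid = NULL,
                                      scatter_sd = NULL) {
  if (n < 5) stop("too few sites: the regression needs at least 5",
                  call. = FALSE)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centroid) || is.null(scatter_sd)) {
    left <- load_electrode_sites()
    left <- left[left$side == "left" & stats::complete.cases(left[, c("x", "y", "z")]), ]
    if (is.null(centroid)) centroid <- colMeans(left[, c("x", "y", "z")])
    if (is.null(scatter_sd)) scatter_sd <- apply(left[, c("x", "y", "z")], 2, stats::sd)
  }
  pos <- cbind(stats::rnorm(n, centroid[1], scatter_sd[1]),
               stats::rnorm(n, centroid[2], scatter_sd[2]),
               stats::rnorm(n, centroid[3], scatter_sd[3]))
  proj <- as.vector((pos - matrix(centroid, n, 3, byrow = TRUE)) %*% direction)
  bias <- gradient * proj + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(id = seq_len(n), side = "left",
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 side_effects = NA_character_, pct_right = NA_real_,
                 init_bias = bias, delta_sac = NA_real_)
}
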