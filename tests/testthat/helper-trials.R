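# shorthand constructors for hand-built trials used across tests

no_saccades <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), x0 = numeric(0),
             y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
             peak_velocity = numeric(0))
}

# trial from a fixation position/duration table; saccades filled in between
fix_trial <- function(x, y = rep(0, length(x)), dur = rep(500, length(x)),
                      condition = "OFF", subject = "s1", image = "i1",
                      peak_velocity = 200) {
  n <- length(x)
  t0 <- cumsum(c(0, head(dur, -1) + 50))
  fx <- data.frame(t_start = t0, t_end = t0 + dur, x = x, y = y)
  sc <- if (n > 1) {
    data.frame(t_start = fx$t_end[-n], t_end = fx$t_start[-1],
               x0 = x[-n], y0 = y[-n], x1 = x[-1], y1 = y[-1],
               peak_velocity = peak_velocity)
  } else no_saccades()
  trial(subject, condition, image, fx, sc, duration = max(fx$t_end) + 100)
}

# trial from a saccade amplitude/direction list (for length metrics)
sacc_trial <- function(amplitudes, angles = rep(0, length(amplitudes)),
                       condition = "OFF", subject = "s1", image = "i1") {
  x <- cumsum(c(0, amplitudes * cos(angles)))
  y <- cumsum(c(0, amplitudes * sin(angles)))
  fix_trial(x, y, condition = condition, subject = subject, image = image)
}

# mirror a trial about the vertical midline
mirror_trial <- function(tr) {
  tr$fixations$x <- -tr$fixations$x
  s <- tr$saccades
  if (nrow(s)) {
    s$x0 <- -s$x0; s$x1 <- -s$x1
    tr$saccades <- s
  }
  trial(tr$subject_id, tr$condition, tr$image_id, tr$fixations,
        tr$saccades[, c("t_start", "t_end", "x0", "y0", "x1", "y1",
                        "peak_velocity")], tr$duration)
}

fast_best <- function(seed = 1, chains = 2, draws = 3000, ...) {
  best_config(chains = chains, draws = draws, warmup = 300, adapt = 300,
              seed = seed, ...)
}
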