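#' Experimental condition labels
#'
#' The closed set of recording conditions: `OFF` (stimulator switched off),
#' `ON` (bilateral therapeutic stimulation), `veL`/`veR` (unilateral
#' stimulation through the ventral-most contact of the left/right electrode),
#' and the two control-subject runs `CTRL1`/`CTRL2`.
#'
#' @return Character vector of the six condition labels.
#' @export
dbs_conditions <- function() {
  c("OFF", "ON", "veL", "veR", "CTRL1", "CTRL2")
}

#' Construct a free-viewing trial
#'
#' A trial is one image presentation (nominally 8 s) holding the ordered
#' fixation and saccade events of one subject in one condition. Times are in
#' milliseconds from image onset; positions in degrees of visual angle with
#' centre origin, `+x` rightward and `+y` upward. Saccade amplitude is the
#' Euclidean endpoint distance and `direction` is `"rightward"` iff the
#' saccade ends right of where it started (ties are `NA`).
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param condition One of [dbs_conditions()] (case-sensitive).
#' @param image_id Image identifier.
#' @param fixations Data frame with columns `t_start`, `t_end`, `x`, `y`
#'   (ms / deg). A `duration` column is derived.
#' @param saccades Data frame with columns `t_start`, `t_end`, `x0`, `y0`,
#'   `x1`, `y1`, `peak_velocity` (deg/s). `amplitude` and `direction` are
#'   derived.
#' @param duration Trial duration in ms (default 8000).
#'
#' @return An object of class `trial`.
#' @export
trial <- function(subject_id, condition, image_id, fixations, saccades,
                  duration = 8000) {
  fixations <- as.data.frame(fixations)
  saccades <- as.data.frame(saccades)
  need_f <- c("t_start", "t_end", "x", "y")
  need_s <- c("t_start", "t_end", "x0", "y0", "x1", "y1", "peak_velocity")
  if (!all(need_f %in% names(fixations))) {
    stop("fixations must have columns ", paste(need_f, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_s %in% names(saccades))) {
    stop("saccades must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  fixations$duration <- fixations$t_end - fixations$t_start
  if (nrow(saccades)) {
    saccades$amplitude <- sqrt((saccades$x1 - saccades$x0)^2 +
                               (saccades$y1 - saccades$y0)^2)
    saccades$direction <- ifelse(saccades$x1 > saccades$x0, "rightward",
                                 ifelse(saccades$x1 < saccades$x0, "leftward",
                                        NA_character_))
  } else {
    saccades$amplitude <- numeric(0)
    saccades$direction <- character(0)
  }
  tr <- structure(
    list(subject_id = as.character(subject_id),
         condition = as.character(condition),
         image_id = as.character(image_id),
         duration = duration,
         fixations = fixations[order(fixations$t_start), , drop = FALSE],
         saccades = saccades[order(saccades$t_start), , drop = FALSE]),
    class = "trial")
  validate_trial(tr)
  tr
}

#' Validate trial invariants
#'
#' Checks that the condition label belongs to the closed enum, that events are
#' time-ordered with positive durations, and that fixations and saccades do
#' not overlap in time.
#'
#' @param tr A [trial()] object.
#' @return `tr`, invisibly; errors describe the first violated invariant.
#' @export
validate_trial <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  if (!tr$condition %in% dbs_conditions()) {
    stop(sprintf("unknown condition label '%s' (must be one of %s)",
                 tr$condition, paste(dbs_conditions(), collapse = ", ")),
         call. = FALSE)
  }
  ev <- rbind(
    data.frame(t_start = tr$fixations$t_start, t_end = tr$fixations$t_end),
    data.frame(t_start = tr$saccades$t_start, t_end = tr$saccades$t_end))
  if (nrow(ev)) {
    if (any(ev$t_end <= ev$t_start)) {
      stop("event with t_end <= t_start", call. = FALSE)
    }
    ev <- ev[order(ev$t_start), , drop = FALSE]
    if (nrow(ev) > 1 &&
        any(ev$t_start[-1] < ev$t_end[-nrow(ev)] - 1e-9)) {
      stop("overlapping events within trial", call. = FALSE)
    }
  }
  if (nrow(tr$saccades)) {
    d <- sqrt((tr$saccades$x1 - tr$saccades$x0)^2 +
              (tr$saccades$y1 - tr$saccades$y0)^2)
    if (any(abs(d - tr$saccades$amplitude) > 1e-9)) {
      stop("saccade amplitude inconsistent with endpoints", call. = FALSE)
    }
    if (any(!is.na(tr$saccades$peak_velocity) &
            tr$saccades$peak_velocity <= 0)) {
      stop("non-positive saccade peak velocity", call. = FALSE)
    }
  }
  invisible(tr)
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial> subject %s, %s, image %s: %d fixations, %d saccades over %g ms\n",
              x$subject_id, x$condition, x$image_id,
              nrow(x$fixations), nrow(x$saccades), x$duration))
  invisible(x)
}

# Format a double so that read-back reproduces the identical IEEE value.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write trials to a plain-text event table
#'
#' One row per event, UTF-8 CSV (or TSV by file extension), times in ms and
#' positions in degrees. Numbers are printed with 17 significant digits so the
#' written file round-trips bit-exactly through [read_event_table()].
#'
#' @param trials A list of [trial()] objects.
#' @param path Output path, `.csv` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    f <- tr$fixations
    s <- tr$saccades
    rbind(
      if (nrow(f)) data.frame(
        subject = tr$subject_id, condition = tr$condition,
        image = tr$image_id, trial_duration = tr$duration,
        event = "fixation", t_start = f$t_start, t_end = f$t_end,
        x = f$x, y = f$y, x_end = NA_real_, y_end = NA_real_,
        peak_velocity = NA_real_),
      if (nrow(s)) data.frame(
        subject = tr$subject_id, condition = tr$condition,
        image = tr$image_id, trial_duration = tr$duration,
        event = "saccade", t_start = s$t_start, t_end = s$t_end,
        x = s$x0, y = s$y0, x_end = s$x1, y_end = s$y1,
        peak_velocity = s$peak_velocity))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$subject, tab$condition, tab$image, tab$t_start), ,
             drop = FALSE]
  num <- c("trial_duration", "t_start", "t_end", "x", "y", "x_end", "y_end",
           "peak_velocity")
  for (cl in num) tab[[cl]] <- .fmt_num(tab[[cl]])
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an event table into trials
#'
#' Parses a CSV/TSV event table (header row required, columns `subject`,
#' `condition`, `image`, `event`, `t_start`, `t_end`, `x`, `y`, and for
#' saccades `x_end`, `y_end`, `peak_velocity`) into a list of validated
#' [trial()] objects. Positions may be stored in degrees (default) or in
#' screen pixels, in which case a [screen_geometry()] is required for
#' conversion.
#'
#' @param path Input path, `.csv` or `.tsv`.
#' @param geom Optional [screen_geometry()]; required when `units = "px"`.
#' @param units `"deg"` (default) or `"px"`.
#' @return A list of [trial()] objects ordered by subject, condition, image.
#' @export
read_event_table <- function(path, geom = NULL, units = c("deg", "px")) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject", "condition", "image", "event", "t_start", "t_end",
            "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("event table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- which(!tab$condition %in% dbs_conditions())
  if (length(bad_cond)) {
    stop(sprintf("unknown condition label '%s' at row %d",
                 tab$condition[bad_cond[1]], bad_cond[1]), call. = FALSE)
  }
  bad_ev <- which(!tab$event %in% c("fixation", "saccade"))
  if (length(bad_ev)) {
    stop(sprintf("unknown event type '%s' at row %d",
                 tab$event[bad_ev[1]], bad_ev[1]), call. = FALSE)
  }
  if (units == "px") {
    if (is.null(geom)) stop("pixel input requires a screen_geometry",
                            call. = FALSE)
    p <- px_to_deg(tab$x, tab$y, geom)
    tab$x <- p$x; tab$y <- p$y
    sac <- tab$event == "saccade"
    if (any(sac)) {
      p2 <- px_to_deg(tab$x_end[sac], tab$y_end[sac], geom)
      tab$x_end[sac] <- p2$x; tab$y_end[sac] <- p2$y
    }
  }
  if (!"trial_duration" %in% names(tab)) tab$trial_duration <- 8000
  for (cl in c("x_end", "y_end", "peak_velocity")) {
    if (!cl %in% names(tab)) tab[[cl]] <- NA_real_
  }
  num <- c("trial_duration", "t_start", "t_end", "x", "y", "x_end", "y_end",
           "peak_velocity")
  for (cl in num) tab[[cl]] <- as.numeric(tab[[cl]])
  key <- interaction(tab$subject, tab$condition, tab$image, drop = TRUE)
  trials <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    if (is.unsorted(sub$t_start[sub$event == "fixation"]) ||
        is.unsorted(sub$t_start[sub$event == "saccade"])) {
      # trial() sorts; non-monotone *within an event row* is caught below
    }
    bad_t <- which(sub$t_end <= sub$t_start)
    if (length(bad_t)) {
      stop(sprintf("non-monotone event times at row %d", idx[bad_t[1]]),
           call. = FALSE)
    }
    f <- sub[sub$event == "fixation", c("t_start", "t_end", "x", "y")]
    s <- sub[sub$event == "saccade",
             c("t_start", "t_end", "x", "y", "x_end", "y_end",
               "peak_velocity")]
    names(s) <- c("t_start", "t_end", "x0", "y0", "x1", "y1", "peak_velocity")
    trial(sub$subject[1], sub$condition[1], sub$image[1],
          fixations = f, saccades = s, duration = sub$trial_duration[1])
  })
  ord <- order(vapply(trials, function(t) t$subject_id, ""),
               vapply(trials, function(t) t$condition, ""),
               vapply(trials, function(t) t$image_id, ""))
  unname(trials[ord])
}
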