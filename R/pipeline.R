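#' Average the two control runs
#'
#' Control subjects are recorded twice with the patients' timing; their
#' per-metric values are averaged across the two runs before any group
#' comparison, so each control contributes one value like each patient.
#' Controls missing a run are excluded (reported via message).
#'
#' @param metrics A tibble with `subject_id`, `condition` (containing
#'   `CTRL1`/`CTRL2` rows) and numeric metric columns.
#' @return A tibble with one row per control subject, condition `"CTRL"`,
#'   and each numeric metric averaged over the two runs.
#' @export
average_control_runs <- function(metrics) {
  ctl <- metrics[metrics$condition %in% c("CTRL1", "CTRL2"), , drop = FALSE]
  num_cols <- names(ctl)[vapply(ctl, is.numeric, TRUE)]
  out <- list()
  for (sid in unique(ctl$subject_id)) {
    sub <- ctl[ctl$subject_id == sid, , drop = FALSE]
    if (!all(c("CTRL1", "CTRL2") %in% sub$condition)) {
      message("excluding control ", sid, ": missing one run")
      next
    }
    r1 <- sub[sub$condition == "CTRL1", num_cols, drop = FALSE]
    r2 <- sub[sub$condition == "CTRL2", num_cols, drop = FALSE]
    avg <- tibble::as_tibble(as.list((unlist(r1[1, ]) + unlist(r2[1, ])) / 2))
    out[[length(out) + 1]] <- tibble::tibble(subject_id = sid,
                                             condition = "CTRL", avg)
  }
  if (!length(out)) {
    return(tibble::tibble(subject_id = character(0), condition = character(0)))
  }
  do.call(rbind, out)
}

# per-subject-condition metric and bias tables for a simulated cohort
.cohort_tables <- function(cohort, bounds) {
  cfg <- bias_config(bounds = bounds)
  met <- list(); bia <- list()
  for (i in seq_len(nrow(cohort))) {
    trials <- cohort$trials[[i]]
    met[[i]] <- oculomotor_summary(trials, bounds = bounds)
    bia[[i]] <- bias_summary(trials, cfg)
  }
  list(metrics = do.call(rbind, met), bias = do.call(rbind, bia))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> (optional sample rendering + event detection) ->
#' oculomotor metrics -> bias measures -> Bayesian contrasts, writing
#' per-stage artifacts and a reproducibility manifest. The pipeline is a
#' pure function of `(config, seed)`: re-running with the same configuration
#' reproduces every output file and the manifest hash bit-identically.
#'
#' The default contrasts mirror the clinical analysis logic: the patients'
#' unstimulated (OFF) state is compared against the average of the controls'
#' two runs (two-group BEST), and the stimulated-vs-unstimulated change is a
#' paired contrast (ON minus OFF).
#'
#' @param config A list or path to a YAML file. Recognised fields (all
#'   optional): `seed`, `out_dir`, `cohort` (arguments for [cohort_spec()]
#'   plus `conditions` to restrict the simulated set and `n_trials`),
#'   `detect` (logical: re-derive events from rendered 500-Hz samples
#'   through [detect_events()] instead of using generator events),
#'   `mcmc` (arguments for [best_config()]).
#' @return Invisibly, a list with `metrics`, `bias`, `contrasts`, `manifest`
#'   (including `manifest$hash`), and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("scanbias_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cc <- config$cohort %||% list()
  base <- scanpath_model(n_trials = cc$n_trials %||% 35)
  spec_args <- cc[intersect(names(cc),
                            c("n_patients", "n_controls", "n_two_condition"))]
  spec <- do.call(cohort_spec, c(spec_args, list(base_model = base)))
  if (!is.null(cc$conditions)) {
    spec$condition_params <-
      spec$condition_params[spec$condition_params$condition %in% cc$conditions, ]
  }
  cohort <- simulate_cohort(spec, seed = seed)

  geom <- screen_geometry()
  if (isTRUE(config$detect)) {
    set.seed(seed + 1L)
    cohort$trials <- lapply(cohort$trials, function(trials) {
      lapply(trials, function(tr) {
        detect_trial(render_samples(tr, geom, noise_sd = 0.05), geom,
                     subject_id = tr$subject_id, condition = tr$condition,
                     image_id = tr$image_id, duration = tr$duration)
      })
    })
  }

  tabs <- .cohort_tables(cohort, bounds = base$bounds)
  metrics <- merge(tabs$metrics,
                   cohort[, c("subject_id", "condition", "group")],
                   by = c("subject_id", "condition"))
  bias <- merge(tabs$bias, cohort[, c("subject_id", "condition", "group")],
                by = c("subject_id", "condition"))
  metrics <- metrics[order(metrics$subject_id, metrics$condition), ]
  bias <- bias[order(bias$subject_id, bias$condition), ]

  mcmc <- config$mcmc %||% list()
  cfg <- do.call(best_config,
                 c(mcmc[setdiff(names(mcmc), "seed")], list(seed = seed)))

  contrasts <- list()
  ctl_avg <- average_control_runs(metrics)
  off <- metrics[metrics$condition == "OFF", ]
  if (nrow(off) >= 3 && nrow(ctl_avg) >= 3) {
    bg <- best_two_group(ctl_avg$mean_saccade_length,
                         off$mean_saccade_length, cfg)
    contrasts$saccade_length_ctrl_vs_off <- .contrast_record(bg)
  }
  on <- metrics[metrics$condition == "ON", ]
  paired <- merge(on[, c("subject_id", "mean_saccade_length")],
                  off[, c("subject_id", "mean_saccade_length")],
                  by = "subject_id", suffixes = c("_on", "_off"))
  if (nrow(paired) >= 3) {
    bp <- best_paired(paired$mean_saccade_length_on -
                        paired$mean_saccade_length_off, cfg)
    contrasts$saccade_length_on_minus_off <- .contrast_record(bp)
  }
  ctl_bias <- average_control_runs(bias)
  off_bias <- bias[bias$condition == "OFF", ]
  if (nrow(off_bias) >= 3 && nrow(ctl_bias) >= 3) {
    bb <- best_two_group(off_bias$global_horizontal_bias,
                         ctl_bias$global_horizontal_bias, cfg)
    contrasts$horizontal_bias_off_vs_ctrl <- .contrast_record(bb)
  }

  # write artifacts
  events_path <- file.path(out_dir, "events.csv")
  write_event_table(unlist(cohort$trials, recursive = FALSE), events_path)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)
  bias_path <- file.path(out_dir, "bias.csv")
  utils::write.csv(bias, bias_path, row.names = FALSE)
  contrasts_path <- file.path(out_dir, "contrasts.json")
  jsonlite::write_json(contrasts, contrasts_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- c(events_path, metrics_path, bias_path, contrasts_path)
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "scanbias",
    version = as.character(utils::packageVersion("scanbias")),
    seed = seed,
    detect = isTRUE(config$detect),
    n_patients = spec$n_patients, n_controls = spec$n_controls,
    n_trials = base$n_trials,
    conditions = spec$condition_params$condition,
    mcmc = list(chains = cfg$chains, draws = cfg$draws),
    files = as.list(stats::setNames(unname(sums), basename(files))))
  tmp <- tempfile()
  writeLines(unlist(manifest$files), tmp)
  manifest$hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(metrics = tibble::as_tibble(metrics),
                 bias = tibble::as_tibble(bias),
                 contrasts = contrasts, manifest = manifest,
                 out_dir = out_dir))
}

.contrast_record <- function(ps) {
  est <- ps$estimates
  key <- intersect(c("mu_diff", "mu"), est$parameter)[1]
  row <- est[est$parameter == key, ]
  es <- est[est$parameter == "effect_size", ]
  list(mean_difference = row$mean,
       hdi = c(row$hdi_low, row$hdi_high),
       effect_size = if (nrow(es)) es$mean else NA_real_,
       significant = hdi_excludes_zero(ps, key),
       rhat = max(est$rhat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
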