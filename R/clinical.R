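#' Lateralized UPDRS-III sums
#'
#' Sums the left- and right-side subscores of the lateralized motor items
#' (items 20-26: tremor and rigidity/bradykinesia items scored per body
#' side). Missing items yield partial sums with a flag.
#'
#' @param items Data frame with columns `item` (integer), `side`
#'   (`"left"`/`"right"`) and `score` (0-4).
#' @return List with `left_sum`, `right_sum` and `partial` (TRUE when any
#'   lateralized item was missing).
#' @export
lateralized_sums <- function(items) {
  need <- c("item", "side", "score")
  if (!all(need %in% names(items))) {
    stop("items must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lat <- items[items$item %in% 20:26, , drop = FALSE]
  sums <- function(s) {
    x <- lat$score[lat$side == s]
    list(sum = sum(x, na.rm = TRUE),
         n = sum(lat$side == s & !is.na(lat$score)))
  }
  l <- sums("left"); r <- sums("right")
  list(left_sum = l$sum, right_sum = r$sum,
       partial = (l$n < 7) || (r$n < 7) || anyNA(lat$score))
}

#' Friedman rank ANOVA over repeated conditions
#'
#' Within-row ranking with mid-ranks for ties and the tie-corrected
#' chi-squared statistic, for a subjects-by-conditions score matrix. Rows
#' with any missing condition are dropped (count reported).
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions.
#' @return List with `chi2`, `df`, `p`, `n` (complete rows) and `n_dropped`.
#' @export
friedman_test_conditions <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  }
  complete <- stats::complete.cases(mat)
  dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 complete rows", call. = FALSE)
  ranks <- t(apply(mat, 1, rank))
  if (all(abs(colSums(ranks) - nrow(mat) * (ncol(mat) + 1) / 2) < 1e-12)) {
    # fully tied rank sums: the statistic is 0 by definition (the tie
    # correction makes the generic formula 0/0 here)
    return(list(chi2 = 0, df = ncol(mat) - 1, p = 1, n = nrow(mat),
                n_dropped = dropped))
  }
  ft <- stats::friedman.test(mat)
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, n = nrow(mat), n_dropped = dropped)
}

#' Pairwise Wilcoxon signed-rank tests with Holm correction
#'
#' Two-tailed signed-rank tests for a family of condition pairs, with
#' Bonferroni-Holm step-down adjustment across the family. Zero differences
#' are dropped (Wilcoxon's rule) and ties handled by mid-ranks; the exact
#' distribution is used below 25 informative pairs, the continuity-corrected
#' normal approximation above.
#'
#' @param mat Numeric matrix, rows = subjects, columns = named conditions.
#' @param pairs List of length-2 character vectors of column names.
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return A tibble with one row per pair: `pair`, `W`, `n_nonzero`,
#'   `p_raw`, `p_adjusted`, `significant`, `degenerate` (all differences
#'   zero).
#' @export
wilcoxon_pairs <- function(mat, pairs, alpha = 0.05) {
  mat <- as.matrix(mat)
  rows <- lapply(pairs, function(pr) {
    d <- mat[, pr[1]] - mat[, pr[2]]
    d <- d[!is.na(d)]
    nz <- sum(d != 0)
    if (nz == 0) {
      return(tibble::tibble(pair = paste(pr, collapse = " vs "),
                            W = NA_real_, n_nonzero = 0L, p_raw = NA_real_,
                            degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(
      mat[, pr[1]], mat[, pr[2]], paired = TRUE,
      exact = nz < 25, correct = TRUE))
    tibble::tibble(pair = paste(pr, collapse = " vs "),
                   W = unname(wt$statistic), n_nonzero = nz,
                   p_raw = wt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !out$degenerate
  out$p_adjusted[ok] <- stats::p.adjust(out$p_raw[ok], method = "holm")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Classical paired t-test
#'
#' @param v1,v2 Equal-length paired numeric vectors (pairs with missing
#'   values dropped).
#' @return List with `t`, `df`, `p`, `mean_difference`, `n`.
#' @export
paired_t <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("v1 and v2 must have equal length",
                                     call. = FALSE)
  keep <- !is.na(v1) & !is.na(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(v1 - v2) == 0) {
    stop("undefined t: paired differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(v1, v2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = unname(tt$estimate), n = length(v1))
}

# type-7 interquartile range (Q3 - Q1, linear interpolation)
.iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Demographic and clinical summary of the patient table
#'
#' Means of age, levodopa-equivalent dose, disease duration, DBS duration and
#' symptom asymmetry; medians with type-7 IQRs for the UPDRS-III columns; and
#' the levodopa-challenge improvement computed as the improvement of medians,
#' `100 * (median_OFF - median_ON) / median_OFF`, over the pre-operative
#' columns (rows with missing scores excluded). Note the improvement of
#' medians differs from the median of per-patient improvements; the former is
#' reported.
#'
#' @param records The [load_demographics()] tibble (or a compatible table).
#' @return A tibble of named summary statistics (`statistic`, `value`).
#' @export
summarize_table1 <- function(records) {
  med_iqr <- function(x) c(stats::median(x, na.rm = TRUE), .iqr7(stats::na.omit(x)))
  pre_off <- med_iqr(records$updrs_preop_dopa_off)
  pre_on <- med_iqr(records$updrs_preop_dopa_on)
  post_off <- med_iqr(records$updrs_postop_dbs_off)
  post_on <- med_iqr(records$updrs_postop_dbs_on)
  tibble::tibble(
    statistic = c("mean_age", "sd_age", "mean_led_mg", "sd_led_mg",
                  "mean_pd_duration_yr", "mean_dbs_duration_yr",
                  "mean_asymmetry_pct",
                  "median_updrs_preop_dopa_off", "iqr_updrs_preop_dopa_off",
                  "median_updrs_preop_dopa_on", "iqr_updrs_preop_dopa_on",
                  "median_updrs_postop_dbs_off", "iqr_updrs_postop_dbs_off",
                  "median_updrs_postop_dbs_on", "iqr_updrs_postop_dbs_on",
                  "levodopa_improvement_pct"),
    value = c(mean(records$age), stats::sd(records$age),
              mean(records$led_mg), stats::sd(records$led_mg),
              mean(records$pd_duration_yr), mean(records$dbs_duration_yr),
              mean(records$asymmetry_pct),
              pre_off, pre_on, post_off, post_on,
              100 * (pre_off[1] - pre_on[1]) / pre_off[1]))
}
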