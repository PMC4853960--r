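#' Regress exploration bias on electrode position
#'
#' Ordinary least squares of the z-transformed bias on the column-demeaned
#' MNI coordinates, `z(bias) ~ b1 x + b2 y + b3 z`, one hemisphere at a
#' time. Rows with missing coordinates or bias are excluded listwise (ids
#' reported); the z-transform uses the included rows' mean and SD only.
#' Because predictors are demeaned and the outcome standardized, the fit is
#' invariant under affine rescaling of the bias and translation of the
#' coordinates.
#'
#' @param sites Electrode-site tibble ([load_electrode_sites()] schema).
#' @param bias_field Which outcome column to model (default `"init_bias"`).
#' @param side Hemisphere to analyse (`"left"` or `"right"`).
#' @return An object of class `regression_fit`: `beta` (named length-3),
#'   `intercept`, `F`, `df` (`c(3, n - 4)`), `p`, `r2`, `n`, `excluded_ids`.
#' @export
bias_position_regression <- function(sites,
                                     bias_field = c("init_bias", "pct_right",
                                                    "delta_sac"),
                                     side = c("left", "right")) {
  bias_field <- match.arg(bias_field)
  side <- match.arg(side)
  s <- sites[sites$side == side, , drop = FALSE]
  bias <- s[[bias_field]]
  ok <- stats::complete.cases(s[, c("x", "y", "z")]) & !is.na(bias)
  excluded <- s$id[!ok]
  s <- s[ok, , drop = FALSE]; bias <- bias[ok]
  if (nrow(s) < 5) stop("need at least 5 complete sites", call. = FALSE)
  if (stats::sd(bias) == 0) {
    stop("degenerate outcome: bias has zero variance", call. = FALSE)
  }
  X <- scale(as.matrix(s[, c("x", "y", "z")]), center = TRUE, scale = FALSE)
  if (qr(X)$rank < 3) stop("singular design: collinear coordinates",
                           call. = FALSE)
  zb <- as.vector(scale(bias))
  fit <- stats::lm(zb ~ X)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    beta = stats::setNames(unname(stats::coef(fit)[-1]), c("x", "y", "z")),
    intercept = unname(stats::coef(fit)[1]),
    F = unname(fs[1]), df = unname(fs[2:3]),
    p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    r2 = sm$r.squared, n = nrow(s),
    bias_field = bias_field, side = side,
    excluded_ids = excluded),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> z(%s) ~ demeaned (x, y, z), %s side, n = %d\n",
              x$bias_field, x$side, x$n))
  cat(sprintf("  beta = (%.4f, %.4f, %.4f) per mm\n",
              x$beta[1], x$beta[2], x$beta[3]))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3f, r2 = %.2f\n",
              x$df[1], x$df[2], x$F, x$p, x$r2))
  if (length(x$excluded_ids)) {
    cat("  excluded (missing data):", paste(x$excluded_ids, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Principal bias axis in MNI space
#'
#' The regression coefficient vector points along the direction of steepest
#' bias change across stimulation sites; normalised it defines the principal
#' bias axis, reported as a line through the site centroid for external 3-D
#' rendering. Sign convention: positive y component preferred, else positive
#' x (the axis is direction-only).
#'
#' @param fit A [bias_position_regression()] result.
#' @param sites The electrode-site tibble the fit used.
#' @return List with `direction` (unit 3-vector), `centroid`, `ranked_axes`
#'   (axis names ordered by absolute component) and `line` (function of the
#'   signed distance t, in mm, returning points `centroid + t * direction`).
#' @export
principal_bias_axis <- function(fit, sites) {
  stopifnot(inherits(fit, "regression_fit"))
  b <- fit$beta
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(direction = stats::setNames(rep(NA_real_, 3), c("x", "y", "z")),
                centroid = NULL, ranked_axes = NULL, line = NULL,
                undefined = TRUE))
  }
  dir <- b / nb
  if (dir["y"] < 0 || (dir["y"] == 0 && dir["x"] < 0)) dir <- -dir
  s <- sites[sites$side == fit$side &
               stats::complete.cases(sites[, c("x", "y", "z")]), ]
  centroid <- colMeans(s[, c("x", "y", "z")])
  list(direction = dir, centroid = centroid,
       ranked_axes = names(sort(abs(dir), decreasing = TRUE)),
       line = function(t) centroid + t * dir,
       undefined = FALSE)
}

#' Regression of a condition-minus-baseline bias difference
#'
#' Fits the same demeaned-coordinate model to the per-patient difference
#' between a stimulation condition's bias and the unstimulated baseline,
#' asking whether the stimulation-induced *change* depends on contact
#' position.
#'
#' @param sites Electrode-site tibble providing coordinates (one side).
#' @param bias_condition,bias_baseline Numeric vectors aligned with
#'   `sites[sites$side == side, ]`: the bias during the condition and during
#'   baseline.
#' @param side Hemisphere.
#' @return A `regression_fit` on the differences.
#' @export
condition_difference_regression <- function(sites, bias_condition,
                                            bias_baseline,
                                            side = c("left", "right")) {
  side <- match.arg(side)
  s <- sites[sites$side == side, , drop = FALSE]
  if (length(bias_condition) != nrow(s) || length(bias_baseline) != nrow(s)) {
    stop("bias vectors must align with the sites of the chosen side",
         call. = FALSE)
  }
  s$init_bias <- bias_condition - bias_baseline
  bias_position_regression(s, "init_bias", side)
}
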