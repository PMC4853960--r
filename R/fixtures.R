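# Checksums of the packaged clinical fixtures; load_* refuse silently
# corrupted copies.
.fixture_md5 <- c(
  table1_demographics.csv = "546aa2110543a4f8b89ad8bb66ff3fd8",
  table2_electrodes.csv   = "b6d3191bcaa6a1baf79f2b315d1874c6")

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "scanbias")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[file]]))) {
    stop("corrupted fixture: checksum mismatch for ", file, call. = FALSE)
  }
  path
}

#' Load the packaged patient demographics table
#'
#' The demographics fixture holds one row per patient (n = 17): age, gender,
#' levodopa-equivalent daily dose (mg), disease and DBS durations (years),
#' pre-operative UPDRS-III under the levodopa challenge (dopa OFF/ON;
#' unavailable for three patients), post-operative UPDRS-III with DBS OFF/ON,
#' symptom asymmetry (% left-sided), the therapeutic stimulation settings and
#' the voltages used for the unilateral ventral conditions (unavailable for
#' patients 2, 10 and 15), plus the age and gender of the matched control.
#'
#' @return A tibble with 17 rows; missing entries are `NA`.
#' @seealso [summarize_table1()], [load_electrode_sites()]
#' @export
load_demographics <- function() {
  tab <- utils::read.csv(.fixture_path("table1_demographics.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) != 17) {
    stop("corrupted fixture: expected 17 demographic rows", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Load the packaged electrode-position table
#'
#' MNI coordinates (mm) of the ventral-most stimulation contacts with their
#' per-side bias outcomes: `pct_right` (% exploration time on the right
#' hemifield during the unilateral condition of that side), `init_bias`
#' (median horizontal first-fixation position, deg) and `delta_sac` (mean
#' rightward minus leftward saccade length, deg). One row per patient and
#' side; patient 17's coordinates are `NA` (imaging could not be
#' co-registered).
#'
#' @return A tibble with 28 rows (14 patients x 2 sides).
#' @seealso [bias_position_regression()]
#' @export
load_electrode_sites <- function() {
  tab <- utils::read.csv(.fixture_path("table2_electrodes.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) != 28) {
    stop("corrupted fixture: expected 28 electrode rows", call. = FALSE)
  }
  ok <- stats::complete.cases(tab[, c("x", "y", "z")])
  bad <- (tab$side == "left" & tab$x >= 0) | (tab$side == "right" & tab$x <= 0)
  if (any(bad & ok)) {
    stop("corrupted fixture: MNI x sign inconsistent with hemisphere",
         call. = FALSE)
  }
  tibble::as_tibble(tab)
}
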