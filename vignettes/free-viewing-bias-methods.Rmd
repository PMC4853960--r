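---
title: "Oculomotor metrics and visuospatial bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor metrics and visuospatial bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanbias)
```

# The scientific problem

Parkinson's disease affects eye movements as well as limb movement. Two
signatures matter here: *saccadic hypometria* — abnormally short saccades —
and a subtle *visuospatial bias*, a systematic rightward shift of visual
exploration seen mainly in patients whose motor symptoms began on the left
body side (reflecting right-hemisphere basal-ganglia degeneration). Deep
brain stimulation (DBS) of the subthalamic nucleus (STN) treats the limb
symptoms; whether it also normalises oculomotor behaviour and attention — and
whether that depends on exactly *where* in the subthalamic region the
stimulating contact sits — is the question this package's pipeline is built
to analyse.

The design it supports: patients freely view natural images for 8 s per
trial (35 images per condition, 500 Hz video-oculography) under four
stimulation conditions — `OFF` (no stimulation), `ON` (bilateral
therapeutic), and `veL`/`veR` (unilateral stimulation of the ventral-most
contact of the left/right electrode, targeting the oculomotor territory of
the ventral STN) — and age-matched controls complete the same protocol twice
(`CTRL1`, `CTRL2`). Because each control is measured twice with the
patients' timing, control values are averaged across runs before any group
comparison (`average_control_runs()`), so every subject contributes one
value per measure.

# Event model and geometry

All positions are degrees of visual angle relative to the screen centre,
`+x` rightward, `+y` upward; times are milliseconds from image onset. Pixel
input is converted with a per-axis arctangent of physical offset over
viewing distance — exact at the ±20 deg eccentricities a 24-inch panel at
65 cm reaches, where a small-angle linear map would already be off by a few
percent. The centre origin is a package convention (raw trackers use a
top-left pixel origin); it makes every bias measure signed with
positive = rightward/upward and makes mirror-symmetry assertions exact, which
the test suite uses heavily.

A `trial()` holds non-overlapping, time-ordered fixations and saccades.
Saccade amplitude is the Euclidean endpoint distance (not path length), and
direction is classified by the sign of the horizontal displacement, with
exact ties excluded from both classes.

# Event detection

Trackers ship their own event parsers, and archived studies often provide
only events; to be self-contained the package re-derives events from raw
samples (`detect_events()`). Positions are smoothed with a 5-sample moving
average, velocities come from a smoothed central difference over a 5-sample
window, and samples are saccadic when speed exceeds 30 deg/s (or
acceleration exceeds 8000 deg/s², the published defaults of the common
video-oculography parser — configurable in `detect_config()`, since
thresholds are assumptions, not facts). Each saccadic run is then grown
outward until speed falls below 30% of the threshold; without this
onset/offset extension the threshold crossing systematically clips the first
and last ~2% of displacement per side. Saccades shorter than 6 ms and
fixations shorter than 50 ms are discarded; invalid (blink) samples are
excised, each valid segment parsed separately, and fixation fragments
flanking a blink merged when their centroids agree within 0.5 deg. The
module's core oracle is the generator round-trip: on rendered 500-Hz samples
with 0.1 deg noise, `calibrate_detection()` recovers 100% of simulated
saccades at or above 1 deg with under 1% mean amplitude error.

# Oculomotor metrics

- **Mean saccade length** — pooled arithmetic mean over the subject's
  saccades (a per-trial-mean option exists; pooled is the default because
  free-viewing trials have similar saccade counts and pooling weighs every
  saccade equally).
- **Within-trial length variability** — the *unscaled* median absolute
  deviation of amplitudes within each trial, `median(|len − median(len)|)`,
  aggregated as the median over trials. The 1.4826 consistency factor is
  deliberately omitted: it rescales every subject identically and cancels
  from all contrasts.
- **Main sequence** — OLS of `log10(peak velocity)` on `log10(amplitude)`
  restricted to 0.1–10 deg, where the log-log relation is linear. Slope and
  intercept are summarised by the definite integral of the fitted line over
  that range, in closed form
  `a(u − l) + b[A(ln A − 1)/ln 10]ˡᵘ`; a numeric-quadrature oracle pins this
  to 1e-9 in the tests. Raw integrals carry units of deg·log10(deg/s);
  `normalize_ms_area()` divides a cohort by its grand mean so the cohort
  averages to 1. Published normalized values near 1.03 imply *some*
  normalisation whose exact form is never stated; this package reports both
  the raw and the grand-mean-normalised value and claims neither matches any
  particular printed number.
- **Directional statistics** — counts and mean lengths of left- vs rightward
  saccades and their difference ΔSac (positive = rightward longer).
- **Explored area** — percentage of the image covered by 1-deg discs around
  fixations on a 0.1-deg grid (per trial, subject median). The 1 deg radius
  approximates the foveal extent and is exposed as an argument because the
  quantity has no canonical definition.
- **Saccade-angle variability** — implemented as the circular MAD of saccade
  directions about the circular mean; this reading is an assumption (the
  quantity is usually reported without a formula) and is flagged as such in
  the documentation.

# Visuospatial bias measures

Three measures per subject-condition, all signed so positive = rightward:

1. **First-fixation bias** — median over trials of the first exploratory
   fixation's horizontal position. The forced pre-stimulus central fixation
   is not exploratory; when a data source includes it, `bias_config(skip =
   1)` drops it. (The generator starts at image onset, so its default is
   `skip = 0`.)
2. **Global horizontal bias** — median horizontal position of all fixations
   after the first. Default aggregation is trialwise medians, then the
   median across trials (robust to uneven trial lengths); a pooled option
   reports the single median over all post-first fixations, since the
   original definition is ambiguous between the two. Both are reported by
   the pooled flag rather than silently chosen.
3. **Right-hemifield exploration fraction** — each post-first fixation
   deposits its duration, smoothed by an isotropic Gaussian kernel
   (SD 0.5 deg), onto a density map; the measure is the right-half mass
   fraction per trial, subject value the median over trials.

Density-map numerics: the grid (0.1-deg cells) is anchored so the midlines
fall on cell *boundaries*, and cell masses are Gaussian-CDF differences over
cell edges rather than sampled densities. Two consequences: hemifield splits
are exact at any resolution (halving the cell size changes fractions by
under 1e-3, and the trialwise fraction has a closed form the grid reproduces
to float precision), and kernels truncated at the image boundary are
renormalised so each fixation contributes exactly its duration — the
mass-conservation invariant `total_mass = Σ durations` holds to 1e-9, not
0.5%. A fixation at +1 deg with a 0.5-deg kernel puts exactly Φ(2) = 0.97725
of its mass on the right half, which the tests assert.

# Robust Bayesian estimation

Group and condition contrasts use robust Bayesian estimation in the BEST
family rather than t-tests: observations are Student-t distributed,
`y ~ t(ν, μ, σ)`, with broad data-scaled priors (normal on μ with SD 1000×
the data SD; uniform on σ over [SD/1000, SD×1000]) and a shifted-exponential
prior on the normality parameter, `ν = 1 + Exp(mean 29)`, so heavy-tailed
data down-weight outliers instead of inflating σ. Three model surfaces:

- `best_two_group()` — per-group (μⱼ, σⱼ) with shared ν; reports μ₁ − μ₂ and
  the standardized effect size `(μ₁ − μ₂)/√((σ₁² + σ₂²)/2)`. Reports
  sometimes print the algebraically lighter `√((σ₁ + σ₂)/2)` denominator;
  that form is dimensionally inconsistent (it averages scales, not
  variances) and is almost certainly a typographical contraction, so the
  variance form is the default and the literal form is available via
  `best_config(effect_size = "printed")` for comparability.
- `best_paired()` — one-group model on within-subject differences.
- `bayes_anova_four()` — hierarchical extension to the four-condition
  design: `y ~ t(ν, β₀ + αⱼ + sᵢ, σ)` with half-Cauchy shrinkage priors on
  the deflection and subject-effect scales. Deflections are recentred to
  sum to zero draw-by-draw (the standard identification; without it the
  intercept and deflections trade off freely and cell means mix
  pathologically). Unbalanced designs — subjects observed in a subset of
  conditions — are handled by the long data format. Whether the original
  four-condition analysis used subject effects is not documented; both
  variants are provided (`subject_effects`), defaulting to the
  subject-effects model because the design is within-subject.

Sampling is MCMC via JAGS (rjags), 4 chains × 10 000 post-warmup draws by
default, seeded per chain so runs are bit-reproducible for a fixed sampler
version. The contract is the posterior, not the algorithm. Convergence gate:
split-R̂ < 1.1 for every reported parameter and effective sample size > 400
for every parameter except ν — ν mixes slowly by construction in robust-t
models, its interval is never used for a decision, and gating it would force
needlessly long chains; non-convergence raises an error (never a silent
report), or a warning if configured.

**Decision rule.** A contrast is "significant" iff its 95% highest-density
interval excludes zero. The HDI is the shortest contiguous window of sorted
draws containing ⌈0.95 n⌉ samples; an endpoint exactly at zero counts as
containing zero (conservative tie rule). Calibration:
`calibrate_hdi_coverage()` simulates 200 parameter sets from the model
family, fits the one-group model with reduced draws, and observes 95.5%
coverage of the true location at seed 1 — within the 95% ± 3% band expected
up to Monte-Carlo error.

# Ordinal clinical statistics

UPDRS-III motor scores are ordinal, so condition effects use the Friedman
rank ANOVA (mid-ranks, tie-corrected — delegated to `stats::friedman.test`,
with the fully tied case returning χ² = 0 explicitly since the generic
formula degenerates to 0/0 there) and pairwise Wilcoxon signed-rank tests
with Bonferroni–Holm step-down correction (`stats::wilcox.test`,
`stats::p.adjust`; exact distribution below 25 informative pairs, continuity
corrected normal approximation above; zero differences dropped per
Wilcoxon's rule). Lateralized sums use items 20–26, the per-side motor
items. Demographic summaries report medians with type-7 (linear
interpolation) IQRs — one convention stated once, because "median ± IQR" in
print never names its quantile rule and small-n IQRs differ across
conventions by up to a point; the packaged table reproduces the published
medians exactly and the DBS-OFF IQR as 20.5 against a printed 21, which is
within that convention gap. The levodopa-challenge improvement is computed
as the improvement of medians, `100·(med_OFF − med_ON)/med_OFF` (63.3% on
the packaged table); the median of per-patient improvements is a different
number and does not match the printed value.

# Electrode-position regression

Whether unilateral-stimulation bias depends on contact location is asked
with OLS: z-scored bias on column-demeaned MNI coordinates,
`z(bias) ~ β₁x + β₂y + β₃z`, one hemisphere at a time, with the overall
F-test and r². Demeaning plus z-scoring make the fit invariant to coordinate
translation and affine bias rescaling (tested). The coefficient vector,
normalised, is the *principal bias axis* — the direction in MNI space along
which bias changes fastest — reported with a fixed sign convention (positive
y preferred) and as a parameterised line through the site centroid for 3-D
rendering. On the packaged table the left-side first-fixation-bias model
gives r² = 0.56 on the 13 complete rows with the axis dominated by the
posterior–anterior (y) direction; published df for this model imply n = 14
while the table prints 13 coordinate rows, so the package reports n and df
explicitly rather than asserting either count. Patient 17 is excluded
listwise (missing coordinates). No multiple-testing correction is applied
across the bias-measure × side family, mirroring the original analysis; the
reports state the family size.

# The synthetic-data generator

No raw gaze recordings are publicly deposited for this design, so the
package ships a generator (`scanpath_model()`, `simulate_cohort()`) whose
*defaults are the study conditions*: 17 patients / 17 controls, three
patients restricted to OFF and ON, 35 8-s trials per condition, 500 Hz.
Per-condition parameters are the published group means — mean amplitude
2.79 deg (OFF), 3.14 (ON), 2.95 (veL/veR, "intermediate"), 3.79 (controls);
horizontal bias 0.89/0.77/0.95/0.48 deg and 0 for controls; first-fixation
bias 0.14 deg for patients and −1.0 deg for controls (the healthy early
leftward bias).

Design choices, each with its reason:

- **Log-normal amplitude and duration laws** (positive support, heavy right
  tail typical of free viewing), parameterised by target mean; the duration
  law defaults to a 280 ms mean, yielding roughly three fixations per
  second — an assumption, since no saccade-rate figure is published.
  A log-normal caps MAD/mean at ≈ 0.367 (at sdlog ≈ 0.9), below the
  published within-trial MAD/mean of ≈ 0.42; the default sdlog 0.75 was
  chosen for realistic spread, so the generator emulates the MAD *contrast*
  at a smaller magnitude than printed. No calibration criterion rests on it.
- **Bias as a rigid stationary shift.** Fixation targets follow a random
  walk: amplitude from the law, direction chosen among uniform proposals
  re-weighted by a centre-seeking Laplace attractor (scales 6/4 deg) that
  keeps scanpaths on the image without hard reflection artifacts. The walk
  runs in bias-centred coordinates and is then shifted by `horizontal_bias`.
  This imposes the exploration bias *without* making rightward saccades
  longer or more frequent — matching the empirical dissociation between the
  viewing bias and directional saccade statistics — and leaves the amplitude
  law untouched (the symmetric-model saccade mean recovers to within 0.01
  deg over 10⁴ saccades).
- **Main sequence** `v_peak = 70·A^0.6` deg/s with 10% log-normal noise —
  mid-range literature values for free-viewing saccades; saccade duration is
  `2A/v_peak`, the duration a raised-cosine velocity profile needs so that
  its peak equals the drawn peak velocity and its integral the amplitude.
  `render_samples()` traces exactly that profile, so detection can be tested
  against ground truth.
- **Between/within-subject variability** — subject offsets (SD 0.69 deg for
  amplitude, 1.0 for bias) plus condition-level jitter (0.55 / 0.3 deg),
  chosen jointly so the emergent group-level effect sizes match the
  published ones: measured CTRL−OFF amplitude d ≈ 1.1–1.3, paired ON−OFF
  SD ≈ 0.8, bias d ≈ 0.88. The published condition means (3.14 vs 2.79)
  differ by 0.35 while the published paired estimate is 0.29; a generator
  can impose only one, and it imposes the condition means.
- **Seeding** — one master seed; every subject-condition cell derives an
  independent substream, so cohorts are bit-reproducible and insensitive to
  evaluation order.

What the generator does *not* emulate: image-content-driven salience (the
original stimuli were content-balanced, so bias is imposed statistically),
smooth pursuit, microsaccades, measurement drift, and the skewness that lets
real controls show a 52% right fraction with a ~0 median. Passing
calibrations therefore demonstrate that the *pipeline* recovers imposed
structure at the study's size — not that real data would show these effects.

# Operating characteristics and problem sizes

`calibrate_recovery()` (20 cohorts at the default conditions, reduced MCMC
draws) yields, at seed 1: the hypometria contrast detected in 95% of
cohorts with mean recovered difference 1.05 deg (truth 1.00); the paired
ON−OFF posterior mean positive in 95% with mean 0.39 (imposed 0.35); the
bias contrast detected in 70%. That 70% is worth dwelling on: at effect
size ~0.8 with 17 per group, a two-sided 5%-level comparison has theoretical
power of only ~0.6–0.7, so a single cohort of this size detects the bias
only somewhat more often than not — a caution against over-reading any one
cohort of this design.

Calibrations and tests use reduced problem sizes chosen to keep the full
suite in a few CPU-minutes: 2 chains × 1500 draws for replicate contrasts,
1 × 1000 for the 200 coverage runs, 45 rendered trials (~1000 saccades) for
the detection round-trip. Production analyses should use the 4 × 10 000
default.

# Known limitations

- The hierarchical four-condition model's exact original specification is
  not public; this package follows the cited method family (sum-to-zero
  deflections, shrinkage priors) and documents that provenance.
- Whether the published global-bias median pooled fixations or took
  trialwise medians first is unknown; both are implemented, trialwise is the
  default.
- Sampler antisymmetry (sign-flipped data) holds to Monte-Carlo error, not
  bit-exactly: JAGS trajectories are not mirror-equivariant.
- No saccade-latency analysis: free viewing has no stimulus-event markers to
  measure latency against.
- EDF and other proprietary binary tracker formats are out of scope; the
  readers accept text event/sample tables only.
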