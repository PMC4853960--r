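Package: scanbias
Title: Oculomotor Metrics and Visuospatial Bias in Free-Viewing Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for free-viewing eye-tracking studies of
    oculomotor control and visuospatial attention, with an emphasis on deep
    brain stimulation cohorts. Detects saccades and fixations from raw gaze
    samples, computes saccade-amplitude statistics, main-sequence fits and
    their definite integral, explored area, and duration-weighted
    fixation-density bias measures (first-fixation bias, median horizontal
    position, right-hemifield exploration fraction). Group and condition
    contrasts are estimated with robust Bayesian models (Student-t BEST and
    an ANOVA-like four-condition extension) summarised by posterior means,
    95% highest-density intervals and effect sizes. Includes ordinal clinical
    statistics (Friedman, Wilcoxon signed-rank with Holm correction),
    electrode-position regression in MNI space, and a seeded synthetic
    scanpath generator for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    graphics,
    jsonlite,
    rjags,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
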