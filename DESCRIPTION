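Package: onoffcsf
Title: Simulated Measurement of ON- and OFF-Pathway Contrast Sensitivity
    with a Bayesian Adaptive qCSF Procedure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse monocular contrast sensitivity
    measurements that separate the ON (luminance-increment) and OFF
    (luminance-decrement) visual pathways.  Implements the four-parameter
    truncated log-parabola contrast sensitivity function and its derived
    metrics (area under the log CSF, cut-off spatial frequency), a
    grid-based Bayesian adaptive estimator with one-step-ahead expected
    posterior-entropy stimulus placement, synthesis of balanced, increment
    and decrement band-pass filtered noise stimuli, a simulated-observer
    cohort generator that reproduces the interocular deficit structure of
    anisometropic amblyopia, and the statistical battery used to compare
    conditions (repeated-measures ANOVA with Greenhouse-Geisser
    correction, paired t tests, Wilcoxon signed-rank tests against unity,
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
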