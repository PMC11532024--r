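---
title: "Measuring ON- and OFF-pathway contrast sensitivity with a simulated adaptive qCSF pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ON- and OFF-pathway contrast sensitivity with a simulated adaptive qCSF pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffcsf)
```

## The scientific problem

The ON and OFF retinogeniculate pathways carry luminance increments and
decrements separately. In amblyopia — a developmental disorder in which
one eye has chronically degraded input — the two pathways may not be
equally affected. A psychophysical way to ask this question is to measure
three monocular contrast sensitivity functions (CSFs) per eye: one with
*balanced* stimuli (bipolar band-pass noise modulating symmetrically
about the background, driving both pathways), one with *increment*
stimuli (only brighter than the background, driving the ON pathway) and
one with *decrement* stimuli (only darker, driving the OFF pathway).
Comparing increment and decrement sensitivity across spatial frequency
then isolates pathway-specific losses.

`onoffcsf` implements the full measurement-and-analysis chain for this
design as a simulation pipeline: the parametric CSF model and its derived
metrics, the Bayesian adaptive estimator that measures a CSF in 100
trials, the stimulus synthesis, a simulated-observer cohort whose ground
truth carries the amblyopic deficit structure, and the statistical
battery. Because every observer is synthetic, the pipeline's bias and
variance are measurable: effects are injected into ground truth, and the
question "does the analysis recover them?" becomes a test.

## The CSF model

Sensitivity is the reciprocal of threshold contrast. The model is the
four-parameter truncated log-parabola. With gain $\gamma$ (peak linear
sensitivity), peak frequency $f_0$ (c/deg), bandwidth $\beta$ (full width
at half maximum, octaves) and truncation $\delta$ (log10 units), the log
sensitivity at frequency $f$ is

$$ S(f) = \log_{10}\gamma - \log_{10}2 \left( \frac{2\,\log_2(f/f_0)}{\beta} \right)^2, $$

with the low-frequency side floored at $\log_{10}\gamma - \delta$; the
truncation never applies above $f_0$. The parabola construction makes
sensitivity exactly halve at $\beta/2$ octaves from the peak. Negative
log sensitivity is meaningful (threshold above 100% contrast) and is kept
— it matters for floor-effect handling below.

Two scalar summaries drive the analyses:

* **AULCSF** — the integral of $\max(S(f), 0)$ over $\log_{10} f$ across
  the measured range (composite trapezoid on 1024 points; the clip at
  zero means unreachable thresholds contribute no area, the dominant
  convention for this metric).
* **Cut-off frequency** — the frequency above the peak where threshold
  contrast reaches 0.5 (sensitivity 2), found by bisection in
  $\log_{10} f$ to $10^{-5}$; censored at the search bound when no
  crossing exists, and flagged (not an error) when the peak itself is
  below criterion.

The test grid is geometric: 12 frequencies on [0.31, 11.77] c/deg for the
amblyope protocol, [0.31, 32.31] for controls. Printed frequency labels
are floor-truncated to two decimals (`format_sf()`): 0.8359 prints as
0.83 and 1.6197 as 1.61, which is the convention that reproduces the
labels the protocol reports. The control grid's published labels are
internally inconsistent with a single 12-point geometric rule, so the
control grid's level count is configurable (12 by default); nothing
downstream depends on the choice.

## The adaptive estimator

The estimator is a grid-based Bayesian procedure. The posterior lives on
a factorial grid over the four parameters (log-spaced in gain, peak
frequency and bandwidth, linear in truncation), initialised uniform. A
trial's response likelihood is a Weibull psychometric function of
contrast $c$,

$$ \Psi(c) = g + (1 - g - \lambda)\,(1 - e^{-(c\,S(f))^{b}}), $$

with guess rate $g = 0.5$ (two-alternative forced choice on stimulus
orientation), lapse rate $\lambda = 0.04$ and slope $b = 2$. These three
are not part of the emulated protocol's public description; the defaults
follow common adaptive-CSF practice and are exposed in `psy_config()`.

Each trial selects, from the experiment frequencies crossed with
log-spaced contrasts, the candidate minimising the one-step-ahead
expected posterior Shannon entropy. The implementation uses the identity

$$ E[H] = H(w) + \bar p \log_2 \bar p + \bar q \log_2 \bar q
   - w^\top\!\big(L \circ \log_2 L + (1{-}L) \circ \log_2(1{-}L)\big), $$

where $L$ is the node-by-candidate probability-correct matrix and
$\bar p = L^\top w$. Both kernels depend only on the measurement
configuration, so they are precomputed once (`likelihood_tables()`) and a
trial costs two matrix–vector products. The tests verify the identity
against brute-force enumeration of both outcomes on small grids.

A run is 5 practice trials at full contrast (recorded, excluded from the
posterior — they are warm-up, not data) followed by 100 adaptive trials.
The estimate is the posterior mean on each axis's natural scale
(posterior means are stable on coarse grids; a MAP option would be more
grid-sensitive). If more than 25% of posterior mass sits on any axis
boundary the estimate carries an edge warning.

### Grid resolutions and why the default is modest

The default grid is 16 × 10 × 7 × 6 ≈ 6,700 nodes; cohort-scale
simulation uses 10 × 8 × 6 × 6 = 2,880 nodes and 30 candidate contrasts
(`study_engine_config()`). We measured per-frequency log-sensitivity
RMSE of single runs at several resolutions and found it essentially flat
from ~3,000 to ~170,000 nodes (the error is information-limited at 100
trials, not resolution-limited; the posterior mean over a coarse grid
even acts as a mild regulariser). The coarse grid was therefore chosen
on accuracy-per-cost grounds. The full-resolution grid used by desktop
implementations (30 × 25 × 15 × 15) is available by passing explicit
axis specifications to `param_grid()`.

### What recovery tests can and cannot show

After 100 trials the median absolute log10 gain error across seeded runs
is below 0.15, and the *fitted curve* improves steadily with trial
count. Individual parameters are another matter: gain, peak frequency,
bandwidth and truncation trade off against each other, so for observers
with broad bandwidth (a flat parabola) the marginal posterior for peak
frequency can drift while the curve itself keeps improving. The
all-four-parameters-improve property is tested with a narrow-bandwidth
observer displaced from the prior anchors, where each parameter is
identifiable; that choice is what makes the test informative about
information accumulation rather than about the prior.

## Stimulus synthesis

Stimuli are band-pass filtered noise: white Gaussian noise convolved
with an oriented Gabor kernel whose half-amplitude spectral full width
is 1.84 octaves (the σ follows from the standard octave-bandwidth
relation for Gabors), in a Gaussian spatial window. Images are matrices
of Weber contrast (0 = background) at 256 × 256 px, 32 px/deg; monitor
physics (gamma, bit depth, viewing distance) is out of scope, so only
degree-based quantities appear.

Polarity is set by half-wave rectification of one balanced noise sample:
increments keep the positive lobes, decrements the negative lobes, so
the two classes are exact sign-mirrors of the same noise. The protocol
description ("brighter/darker filtered noise than the background") does
not disambiguate rectified noise from noise on a pedestal; rectification
is the default because it preserves the filtered-texture appearance and
changes mean luminance equally (and minimally) for both polarities.
"Contrast" for unipolar stimuli is the peak Weber deviation, which makes
increment and decrement symmetric and maps directly onto the estimator's
contrast axis. Rectification broadens the spectrum (and adds a DC/low-
frequency component) but does not shift the passband peak by more than
half an octave — verified spectrally in the tests.

Note the adaptive engine itself is abstract over rendering: it works in
(frequency, contrast) space. The raster layer exists to validate the
stimulus class definitions and for export (`export_stimuli()`).

## The simulated cohort

`cohort_config()` defaults encode the emulated study conditions:

* 11 amblyopes, 10 controls;
* ground-truth interocular AULCSF ratio (affected/better eye) with
  cohort mean exactly 0.67 for amblyopes and 0.91 for controls
  (per-subject ratios are drawn with SD 0.06 and recentred; the better
  eye's gain is then rescaled by root finding so each subject's ratio is
  exact);
* unipolar (increment/decrement) gain at 0.5 × the balanced gain, with
  0.03 log10 per-condition jitter — unipolar stimuli drive one pathway
  instead of two, and the emulated study found both unipolar CSFs well
  below the balanced one;
* an ON-pathway deficit only in the amblyopic eye: the target
  increment/decrement sensitivity ratio declines log-linearly from 1.0
  at 0.31 c/deg to 0.7 at 2.25 c/deg and stays at the floor beyond. The
  increment CSF is refitted against the decrement CSF by least squares
  over (gain, bandwidth) on the window frequencies. A two-parameter
  log-parabola adjustment cannot also return the ratio to unity beyond
  the knee, so outside the window the realised ratio drifts upward;
  those frequencies are excluded from the ratio analysis anyway (that is
  what the threshold-below-1 window is for). The realised window
  geometric-mean ratio tracks the target within 0.05 log10 units.
* between-subject SDs of 0.15 log10 on gain and 0.1 log10 on peak
  frequency — not published values; chosen once to give AULCSF spreads
  of plausible magnitude for adult cohorts.

Responses are Bernoulli draws through the same Weibull psychometric
function the estimator assumes (no model mismatch — recovery failures
would therefore indicate pipeline defects, not misspecification).
Seeds derive deterministically per (subject, eye, condition, repetition)
from one master seed, so any single run is reproducible in isolation.
Each condition is measured twice and repetition averaging happens at the
level of derived metrics (AULCSF, log sensitivities, log cut-off), not
raw posteriors, mirroring how repeated sessions are averaged in practice.

## Statistics

All tests return a common one-row schema (`stats_report`).

* `paired_t()` — two-sided paired t; both Cohen's d conventions are
  reported ($d_z = t/\sqrt{n}$ and the pooled-SD d) because published
  effect sizes for this design match neither convention unambiguously.
* `wilcoxon_vs_const()` — signed-rank test against a constant (unity for
  ratio curves). Zeros dropped, average ranks for ties, Z from the
  normal approximation with tie-corrected variance and no continuity
  correction; the p value is exact (full sign enumeration) for n ≤ 10
  and the normal approximation beyond. The tie-free maximal case at
  n = 11 gives Z = 33/√126.5 = 2.934.
* `rm_anova()` — fully within-subject ANOVA for up to three factors via
  orthonormal-contrast decomposition; each effect is tested against its
  subject-by-effect stratum. Greenhouse–Geisser ε is estimated from the
  covariance of the subject contrast scores and applied unconditionally
  to any effect with more than one numerator df (a 2-level effect has
  ε = 1 exactly). Partial η² = SS_effect/(SS_effect + SS_error). The
  implementation is cross-checked in the tests against `car::Anova`
  (SS, ε, corrected p) and against a hand-computed SS oracle.
* `inc_dec_ratio()` — per subject, eye and frequency, the ratio of
  repetition-averaged increment to decrement sensitivity, restricted to
  the analysis window. `window = "printed"` fixes the per-group windows
  (0.31–2.25 c/deg amblyopes, 0.31–11.96 controls); `window = "auto"`
  keeps frequencies where both group-mean thresholds are below 1.

### Why cohort ratio curves use geometric means

A measured per-subject ratio is $10^{\Delta}$ where $\Delta$ is the
difference of two log-sensitivity estimates. At 100 trials per run the
estimation noise on $\Delta$ is ~0.15–0.2 log10 units, so measured
ratios are approximately lognormal and their *arithmetic* mean is biased
upward by $10^{\sigma^2 \ln 10 / 2}$ — about 6–15% — at any grid
resolution. `ratio_geomeans()` therefore summarises cohort ratio curves
by geometric means, which are unbiased on the log scale and consistent
with the median-based signed-rank test. The interocular AULCSF ratio
stays an arithmetic mean (matching the 0.67/0.91 convention); AULCSF
noise is small enough that its lognormal correction is negligible.

## Problem sizes used in the tests

Parameter recovery uses 20 seeded runs at the default grid. Effect
propagation uses: one balanced-condition study (21 subjects × 2 eyes ×
2 repetitions) for the interocular-ratio check; 20 replicate cohorts
(amblyopic eye, increment + decrement, 2 repetitions) for the
direction-of-effect check; and 20 null-cohort replicates for the
unbiasedness check. These sizes were chosen so that each check's
expected failure probability under correct behaviour is a few percent
or less while a full test run stays desk-scale.

## Known limitations

* The simulated observer shares the estimator's psychometric model;
  robustness to slope/lapse misspecification is not evaluated.
* The ON-deficit profile's between-subject variability is a free
  default (no published per-subject variability exists to emulate).
* The generator injects the deficit into increment sensitivity only,
  leaving the decrement CSF at the unipolar baseline; a shared-pathway
  deficit with a smaller ON-specific component would look identical in
  the ratio analysis.
* Human-data headline statistics (specific F and p values) depend on the
  deposited human dataset and are out of scope; the pipeline reproduces
  the *structure* of those analyses on synthetic cohorts, plus the
  printed quantities that are recomputable analytically.
* Stimulus rasters are validated spectrally and by polarity invariants,
  but no ideal-observer link between raster and the (frequency,
  contrast) abstraction is modelled.
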