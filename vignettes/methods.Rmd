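---
title: "Measuring and validating orientation-identification thresholds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and validating orientation-identification thresholds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visagree)
```

## The scientific problem

Web-based psychophysics promises cheap, scalable measurement of visual
function, but a threshold measured on a participant's own monitor at home is
only useful if it agrees with the threshold the same person would produce
under controlled laboratory conditions. `visagree` models the full
measurement chain for one well-studied probe of early visual cortex — the
*oblique effect* in a two-alternative forced-choice (2AFC)
orientation-identification task — and implements the statistical machinery
needed to (a) detect the effect at the group level and (b) quantify web/lab
reliability and agreement at the individual level.

The package contains no display code: it models the *design* of the task
(trial scheduling, stimulus geometry) and analyses the resulting trial
records, whether those come from real experiment software or from the
built-in synthetic observer.

## The task model

Each orientation condition fixes a standard orientation (0°, 90°, −45° or
+45°, measured anticlockwise from horizontal) and presents, on every trial, a
standard Gabor and a comparison rotated by one of seven fixed offsets
(method of constant stimuli). Cardinal standards use offsets of 0.71–5.00°,
obliques 3.57–25.00°, reflecting the several-fold threshold difference
between the two classes. A run holds ten repeats of the seven levels in
random order; five runs give 350 trials per condition. The offset sign
(clockwise/anticlockwise) and the position of the standard (first/second
interval in the temporal task; left/right location in the spatial task) are
randomised independently per trial.

`design_config()` carries all of this, plus the stimulus parameters
(1 cyc/° grating, Gaussian envelope with σ = 1.33° truncated at ±4°, 40%
contrast) and timing metadata. Timings are metadata only — nothing is
presented in real time. Display standardisation uses the exact
`2·d·tan(0.5°)` conversion from viewing distance and pixel density rather
than the small-angle approximation, so the geometry stays correct at the 8°
eccentricity of the spatial task. Because every analysis treats the two
obliques symmetrically, the angular reference for ±45° is inert; it is
recorded in the config for transparency.

## The psychometric model

Performance per condition is summarised by proportion correct per offset
level, pooled over runs and offset signs (the counts are sufficient
statistics for everything downstream). The percent-correct curve is the
two-parameter logistic

$$y = 50 + \frac{50}{1 + e^{(x - a)/b}},$$

rising from the 50% chance floor to 100%, with midpoint $a$ — the threshold,
since $y(a) = 75$ exactly — and slope $b$. As printed, the curve increases
only when $b < 0$; the fitter works with the slope magnitude $\beta = -b > 0$
internally and reports both, which removes a sign trap without changing the
model. There is no lapse parameter: the upper asymptote is fixed at 100%.

Fitting minimises the unweighted sum of squared errors on the percent scale
(Levenberg–Marquardt, with a Nelder–Mead fallback; failures are flagged
`converged = FALSE`, never raised). Start values are deterministic and
scale-aware: $a_0$ from linear interpolation of the 75% crossing, $\beta_0$
a quarter of the offset range.

**Threshold standard error.** The SE of $a$ comes from the asymptotic
least-squares covariance (analytic Jacobian). When per-level trial counts
are available the error variance per level is taken as the model-based
binomial variance in a sandwich estimator; proportions near the ceiling are
far less variable than near the midpoint, and ignoring that
heteroscedasticity (or estimating a common variance from 5 residual degrees
of freedom) produces badly calibrated intervals. With the design's 50
trials/level and Weber-like slopes, the ±2 SE interval covers the generating
threshold in ≈95% of simulated conditions. A trial-resampling bootstrap
(`bootstrap_se()`) is available as a cross-check.

**Exclusion.** A participant is excluded when any required condition fails
to "reach threshold": maximum observed proportion below 75%, a
non-converged fit, or a fitted threshold outside the tested offset range.
The 75% performance floor is the criterion; operationalising "reaching
threshold" through the in-range converged fit is a package decision, made
so that the rule is checkable from the data alone and symmetric across
conditions. Missing conditions count as failures, never silent passes.

## The synthetic observer

The generator exists so that every downstream stage can be exercised, end to
end, without human data. Log thresholds follow a crossed random-effects
model per (task, orientation-class) cell:

$$\log a_{i,s,c} = \mu_c + S_i + E_{i,s} + \varepsilon_{i,s,c},$$

with subject effect $S_i \sim N(0, \sigma_S^2)$ shared across sessions,
session effect $E_{i,s}$ shared across the conditions of one session, and a
per-cell residual. Thresholds are therefore log-normal — positive, with
variability proportional to magnitude, which is exactly the structure that
motivates the log-scale agreement analysis. For a single condition the true
between-session intraclass correlation is
$\sigma_S^2 / (\sigma_S^2 + \sigma_E^2 + \sigma_\varepsilon^2)$, so the
generator's reliability is a single controllable dial (`icc`), with the
session-level variance split equally between $E$ and $\varepsilon$ by
default.

Defaults are fixed package choices of what a realistic young-adult sample
looks like on this task: geometric-mean thresholds of 1.2° (temporal
cardinal), 6° (temporal oblique), 1.8° (spatial cardinal), 9° (spatial
oblique) — a strong oblique effect and a temporal-task advantage, each mean
comfortably inside its condition's offset range — between-subject SD 0.35 on
the log scale, true ICC 0.9, and slope magnitude $0.3a$ (constant Weber-like
shape on a log-offset axis). Web and lab are exchangeable by default (no
systematic bias, mean lab/web ratio 1); a multiplicative `session_bias` and
a second-session `learning_gain` exist so that bias detection and the
learning check can themselves be tested. Responses are Bernoulli draws from
the logistic at each scheduled offset.

What the generator does *not* emulate: attentional lapses (no lapse rate),
sequential dependencies, fatigue or drift within runs, display-specific
artefacts, and heavy-tailed between-subject outliers. Passing tests
demonstrate that the analysis machinery is correct and well calibrated under
the stated model — not that real web data satisfy that model.

## Group inference

The web-experiment analysis is a balanced 2 (task) × 4 (orientation)
within-subjects ANOVA, computed by the classical decomposition (subject,
task, orientation, interaction, and subject-by-effect error strata — the
sums of squares are checked against a direct-summation oracle in the test
suite). Sphericity of each within effect is tested with Mauchly's $W$
(first-order $\chi^2$ approximation); Greenhouse–Geisser $\hat\varepsilon$
comes from the orthonormal-contrast covariance and is applied to the
degrees of freedom whenever Mauchly's test rejects at 0.05, mirroring
standard practice; both corrected and uncorrected p values are always
retained. Effect size is partial $\eta^2$. Huynh–Feldt is deliberately out
of scope.

Pairwise follow-ups are paired t tests with Bonferroni multiplication
(capped at 1). Cohen's d is reported under two documented conventions —
$d_{av}$ (mean difference over the average condition SD, the headline
value) and $d_z$ (mean difference over the SD of differences) — because
printed d values in the applied literature are frequently irreproducible
from the t statistics alone and the convention must be explicit.

## Agreement and reliability

Reliability is ICC(2,1): single-measurement, absolute agreement, two-way
random effects, estimated from the mean squares of the subjects × sessions
layout with the standard F-based 95% CI. One threshold pair per
(participant, orientation) enters per task, so each task's ICC pools the
four orientation conditions as separate rows; a `pooled` switch collapses
tasks too.

Agreement is Bland–Altman on natural-log thresholds: the antilogged mean
difference is the mean lab/web ratio (values above 1 = larger thresholds in
the lab), and antilogged mean ± 1.96 SD are ratio-scale limits of agreement.
The natural log is presentation-only — every reported quantity is a
base-invariant ratio. Shapiro–Wilk checks normality of the log differences;
violation warns and flags but does not suppress the limits, since no
remedial transform is defined for this design. The median absolute ratio
$\exp(|\Delta \log|)$, with IQR, serves as a typical-error metric that is
≥ 1 by construction and invariant to swapping the session labels.

The learning check antilogs the mean first-minus-second session log
difference across all participant-conditions; session order is
counterbalanced in the generator exactly as in a crossed validation design.

**Sample-size planning.** `sample_size_icc()` implements the
Walter–Eliasziw–Donner F-based formula for testing an acceptable against an
expected reliability with $k$ ratings per subject — the computation behind
the standard reliability sample-size tables. `alpha` is the one-sided
significance level of that test, which is how those tables are constructed;
with acceptable ICC 0.50, expected 0.75, $k = 8$ and power 0.80 the planner
returns 15 subjects.

## Numerical choices and degenerate inputs

* Logistic fitting bounds $\beta \ge 10^{-8}$; flat (all-chance) data return
  a non-reaching fit rather than an error.
* Sandwich variances clamp fitted proportions to $[1/4n, 1 - 1/4n]$ to avoid
  zero variance at the ceiling; numerically negative variances yield `NA`
  SEs, never NaN warnings.
* Greenhouse–Geisser $\hat\varepsilon$ is clamped to its theoretical range
  $[1/(k-1), 1]$; two-level factors have $W = 1$, $p = 1$ by construction.
  With fewer subjects than contrast dimensions Mauchly's $W$ is undefined
  and reported `NA` with $\hat\varepsilon$ still available.
* ICC matrices must be complete — no imputation; the CI at a degenerate
  estimate of 1 is returned as computed (possibly `NaN`) rather than
  invented.
* All randomness is seeded through a single master seed per invocation;
  stage-specific child seeds are derived from it so population draw,
  scheduling and responses have independent streams.

## Problem sizes used in the tests

The test suite and the verification checks simulate at the design's own
scale where the property being checked demands it (350 trials per condition
for recovery error; 18 participants for the oblique-effect property; 200
subjects × 500 replicates for ICC calibration; 10⁴ pairs for
limits-of-agreement coverage) and at reduced scale elsewhere, chosen as the
smallest sizes at which the Monte-Carlo error is comfortably below the
tolerance being asserted.

## Known limitations

* The least-squares fit matches the published analysis convention; a
  binomial-likelihood fit would be more efficient at extreme proportions
  and is not currently offered.
* The exclusion rule also excludes participants whose threshold falls
  *below* the smallest tested offset (performance too good to measure);
  with the default cardinal offsets this is rare but possible.
* ICC(2,1) pooling orientations within a task mixes the large
  cardinal/oblique mean split into the subject stratum, which inflates the
  ICC relative to a per-condition analysis; this mirrors the pooled design
  of validation studies but should be kept in mind when interpreting the
  estimate.
* The group ANOVA is computed on raw (not log) thresholds, matching common
  practice for this analysis; with log-normal data its normality assumption
  is approximate, which is one reason sphericity corrections matter here.
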