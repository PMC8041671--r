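---
title: "Scroll-pattern analysis of volumetric image reading logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scroll-pattern analysis of volumetric image reading logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Data model

The unit of observation is one resident answering one CT-scan question on
one progress test. The viewer log is an ordered stream of time-stamped
events, each recording the viewing axis (sagittal `x`, coronal `y`, axial
`z`) and the 1-based slice number put on screen. Display state is
**piecewise constant**: the `(axis, slice)` shown at time `t` is that of
the latest event at or before `t`, holding until the next event or until
the question is left (`question_end_ms`). Pan, zoom and window-level
events may appear in logs (`event_kind = "other"`); they carry no slice
semantics, are preserved on read/write, and are ignored by every metric —
a property enforced by metamorphic tests that inject such rows and assert
unchanged results.

Normalisation on construction shifts times so the first event is at 0,
sorts stably by time, and collapses simultaneous display events keeping
the last (the screen shows one slice at a time). Normalisation is
idempotent. Logfiles are plain delimited text with a header and a final
`end` row carrying the question-leaving time, one file per
resident-question pair.

## Full runs

Within each maximal single-axis viewing episode, the slice trajectory is
reduced to its local extrema; consecutive repeats (plateaus, which
sampled piecewise-constant logs produce constantly) are collapsed to the
plateau's first timestamp before reversal detection, so they cannot
create spurious extrema. A *run* connects consecutive extrema; its
duration is the time between their timestamps, so runs tile the span
between an episode's first and last extremum without gaps or overlap.
Time after the last extremum is stationary dwell and belongs to no run.

A run is **full** when its slice distance exceeds half the slice count:
`delta > 0.5 * N`, with a strict inequality, so a traversal of exactly
half the stack is not full. Choices worth stating explicitly:

* The threshold uses the slice count of *the episode's own axis*: a full
  run is a sweep through the stack actually being scrolled. For
  multi-axis questions an alternative reading — always thresholding
  against the axial count — is available via `threshold_axis=`.
* Axis changes terminate runs; slice-number differences across axes are
  meaningless.
* `PercTimeFullRuns` divides the summed duration of full runs by the
  total time on the question (first display to `question_end_ms`). A
  question with zero total time raises an undefined-metric error rather
  than returning a value.

`segment_runs()` is verified against an independent brute-force reference
that scans every index for direction reversals, on thousands of random
trajectories.

## Relevant-area time

Question-relevant areas are per-axis lists of inclusive slice intervals,
fixed by experts; they are data, not something the package derives (how a
relevant axial range projects onto sagittal/coronal views is a property
of the anatomy, so per-axis interval lists are required inputs). Relevance
at any moment is judged on the *currently displayed* axis only; time on
an axis whose interval list is empty is irrelevant time. Dwell is accrued
over half-open display intervals `[t, t')` with the final interval closed
at `question_end_ms`, which makes total time conserve exactly and gives
the complementarity identity — a region and its complement account for
100% of any log — that the test suite asserts. A per-millisecond
simulation of display state serves as the independent oracle.

`relevant_volume_fraction()` measures the region's coverage on a
reference axis (default axial, the viewer's default direction); the
question filter keeps only questions with coverage strictly below one
half, restricting analyses to focal abnormalities.

## Cohort assembly

Questions enter the analysis when they (1) concern a single CT scan,
(2) require a diagnosis, and (3) have relevant-volume coverage < 0.5.
Training time is standardised to a five-year program,
`(test date − start) / (end − start) × 5` in whole days, kept continuous
everywhere except the binned descriptive table. Test difficulty is the
mean item P value of the questions entering the accuracy aggregation,
minus 0.5. Aggregation to resident-by-test records takes unweighted means
of the two scroll metrics over questions with an available logfile
(missing logfiles are dropped listwise); diagnostic accuracy is counted
as `n_correct` of `n_questions` over formats not excluded. Excluding
marker questions (the accuracy analyses' convention, since marker items
couple relevant-area dwell to the answer itself) removes them from the
accuracy counts and from the per-test difficulty, while the scroll-metric
averages keep all selected questions; both variants are reproducible via
`exclude_formats=`.

## Longitudinal models

Both scroll metrics use a two-level Gaussian model — test occasions
within residents — fitted by full maximum likelihood with `lme4`, as a
nested ladder: intercept-only; + training time; + test difficulty;
+ random training-time slope (unstructured 2×2 covariance with the
intercept, since nothing fixes the covariance to zero a priori). Forward
selection uses likelihood-ratio tests on the deviance at `alpha = 0.05`,
the conventional criterion for full-ML nested ladders; non-significant
extensions keep the simpler model.

Fixed-effect standard errors are cluster-robust (CR0 sandwich) by
resident, guarding against non-normal level-1 residuals:
with `V_g = Z_g D Z_g' + sigma^2 I` per resident,
`vcov = B^{-1} (sum_g u_g u_g') B^{-1}` where
`B = sum_g X_g' V_g^{-1} X_g` and `u_g = X_g' V_g^{-1} r_g`. No installed
package provides cluster-robust covariance for `merMod` objects, so this
is implemented here and tested for agreement with model-based standard
errors on correctly specified homoscedastic simulations. p values use the
normal approximation.

Diagnostic accuracy uses a binomial two-level model with logit link: the
level-1 variance is fixed by the binomial assumption and the resident
intercept is random — the standard reading of a proportion outcome over
occasions within persons. Estimation uses adaptive Gauss–Hermite
quadrature with 20 nodes; the random-slope extension necessarily falls
back to the Laplace approximation, which is the most accurate method
`glmer` offers for vector-valued random effects. Fits with exploding
estimates (complete separation, e.g. an all-correct cohort) are flagged
and skipped by model selection. A sufficiency identity — the aggregated
binomial fit equals the fit on exploded 0/1 item rows — is asserted in
the tests.

Effect size is the level-1 explained variance,
`(sigma2_e[null] − sigma2_e[fit]) / sigma2_e[null]` against the
unconditional means model, floored at zero. A heterogeneous level-1
variance (modelling `sigma2_e` as a function of training time) is a
documented non-goal: it neither resolves mild heteroscedasticity in this
design nor has a theoretical basis.

An `lmer`/`glmer` convergence note: optimizer warnings about a marginal
gradient are rescued as converged when the Hessian-scaled relative
gradient is below 1e-3 — the usual false alarm when covariates live on
very different scales — while boundary (singular) fits count as
converged, a variance component on the zero boundary being a legitimate
ML solution.

## Synthetic data

**Trajectories.** A generated question log has three phases: full sweeps
through the entire stack, oscillation between adjacent slices inside the
relevant interval, and stationary dwell on a nearby irrelevant slice. The
sweep time is set by the full-run target; the oscillation time is solved
so that total relevant dwell — *including* what the sweeps accrue while
crossing the relevant interval — matches the relevant-area target; the
rest is irrelevant dwell. Sweeps end at the stack extreme nearest the
relevant region so that the jump to the oscillation anchor can never
itself constitute a full run. Target pairs that cannot coexist (relevance
below the sweep-implied floor, or targets exceeding the question time)
raise an explicit infeasibility error. Question time is log-normal with
mean 122.9 s and SD 124.1 s, the observed distribution of time on CT-scan
questions, truncated to 5–900 s. Realism is deliberately minimal — the
phases exercise the metrics; no saccade-level or strategy-level behaviour
is modelled — so passing tests demonstrate correctness of the measurement
pipeline, not fidelity to human scrolling.

**Cohorts.** Macro-level records are drawn directly from the growth
models with defaults equal to the published estimates: full-run outcome
(20.19, −0.94 per training year, 6.70 per difficulty unit; variances
81.56 / 10.84), relevant-area outcome (53.16, 1.70, −57.47; 133.04 /
5.30), and accuracy on the logit scale (−1.078, 0.338, 0.001, 0.003,
5.093; intercept variance 0.056). Test difficulty is Normal(0.14, 0.07)
truncated to [0.02, 0.24]; tests are semi-annual; each test carries 2–9
questions with mean 5 (2 + Binomial(7, 3/7)). Gaussian outcomes are *not*
truncated to [0, 100]: the fitted model is linear and unbounded, and
truncation would bias parameter recovery; the rare out-of-range value is
a property of the model being emulated, not of the measurement pipeline
(whose outputs are bounded by construction).

Enrolment dates are uniform over the nine years ending at the last test,
so relative training time covers the whole (0, 5] scale. A resident is
eligible for the consecutive tests falling within their five-year
program — which alone would give five tests on average — and attends a
consecutive block of them with an attendance rate of 0.82, reproducing
the observed unbalanced panel of 1–9 tests per resident with mean near
4.1 while keeping participation consecutive.

**Micro cohorts** compose the two: each resident-by-test record's
generated metrics become per-question trajectory targets (jittered, then
clamped into the feasible box of the question's geometry), every resident
of a test answers the same generated question set, and answers are drawn
from the accuracy model. The result is a complete on-disk or in-memory
fixture the whole pipeline can consume.

## Numerical conventions and degenerate inputs

* Times are integer milliseconds; percentages are kept at full double
  precision and rounded only for display.
* Date arithmetic is in whole days.
* Slice indexing is 1-based and inclusive everywhere.
* Zero-duration questions, empty event streams, logs without a display
  event, empty P-value sets and unknown predictors raise errors rather
  than propagate NaN.
* Overlapping or adjacent relevant intervals are merged on construction
  (via `IRanges`), so interval sets are canonical.
* All generators take explicit seeds; sub-seeds drawn for replicates stay
  below 2^31.

## Problem sizes used in the validation suite

Parameter-recovery checks use twenty replicate cohorts of 650 residents —
large enough that the Monte-Carlo standard error of the mean recovered
training-time slope is a few hundredths of a percent point. End-to-end
direction checks run twenty micro cohorts of 80 residents with 30 ± 12 s
questions and a 1.5 s oscillation period, sizes chosen to give the
trend-sign tests high power while the full suite stays fast enough to run
routinely. Oracle-equivalence suites use 1000 random trajectories of up
to 50 events on stacks of up to 30 slices.

## Known limitations

* The within-resident dispersion of training time in the generator only
  approximates the study design it emulates, so level-1 explained
  variance is reproduced in magnitude (bracketed, not point-matched); the
  full-run model's R² is particularly sensitive to that dispersion.
* The three-level (item-level) model is intentionally absent: with
  partially overlapping cohorts across test waves, between- and
  within-resident comparisons would be confounded at the test level, so
  aggregation to resident-by-test records is the valid unit of analysis.
* Generated trajectories are single-axis; multi-axis episode handling is
  exercised by hand-built logs in the tests rather than by the generator.
* One structural caveat on a tempting invariant: inserting a full sweep
  into the *middle* of an ongoing run can split that run and lower the
  full-run percentage; the monotonicity property holds (and is tested)
  for sweeps added during stationary dwell.
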