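---
title: "Models and methods behind ocusimon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ocusimon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocusimon)
```

## The task and the analysis it requires

In an oculomotor Simon task a coloured square appears 12 degrees left or
right of fixation and the participant responds with a left or right saccade
according to the *colour*, ignoring the *location*.  When the location and
the colour-instructed side disagree (incongruent trials), the location
primes the wrong saccade: latencies grow and errors multiply, especially
among the fastest responses.  The standard analysis of such conflict data is
distributional: conditional accuracy functions (CAFs) plot accuracy per
latency septile and expose fast "capture" errors, and delta plots track the
incongruent-minus-congruent latency difference of correct trials across
septiles, whose decline indexes the gradual build-up of selective
inhibition (the activation-suppression account).

`ocusimon` implements that analysis end to end — saccade detection from raw
gaze samples, response extraction, exclusion rules, CAFs, delta plots and
mixed-effects inference — together with a generative simulator so that every
stage can be tested against ground truth without access to any participant
recordings.

## The trial simulator

### Accumulator

Each trial is a one-dimensional diffusion race between two bounds.  With
evidence $X$ (positive toward the correct response) and 1-ms Euler steps,

$$X_{t+\Delta} = X_t + \mu_c\,\Delta + s\,[a(t+\Delta) - a(t)]
  + \sigma \sqrt{\Delta}\,\varepsilon_t,$$

where $\mu_c$ is the controlled (instruction-driven) drift, and

$$a(t) = A\,\frac{t}{\tau}\,\exp\!\left(1 - \frac{t}{\tau}\right)$$

is a pulse of automatic, location-driven activation that peaks at $t=\tau$
with height $A$ and then decays — the "activation, then suppression" shape.
The sign $s$ is $+1$ on congruent and $-1$ on incongruent trials.  The trial
ends when $|X| \ge b$; a positive crossing is correct.  Latency is the
crossing time plus a non-decision time that is defined to end at saccade
onset, so simulated latency is saccade latency.  Trials that do not cross
either bound within 1500 ms are returned as no-response and excluded
downstream.

The starting point $X_0$ is drawn per trial from a symmetric Beta(3, 3)
distribution scaled to $\pm 0.6\,b$.  This is the standard ingredient of
diffusion models for conflict tasks and it matters here: with a fixed
starting point, the only fast incongruent errors are trials in which the
pulse itself captured the response, and conditioning the delta plot on
*correct* trials then censors exactly the fast incongruent trials the first
septile needs — the simulated delta plot flattens between bins 1 and 2.
Starting-point variability produces fast errors in the trials that start
near the wrong bound while leaving the remaining fast correct trials
pulse-delayed, which restores the empirically ubiquitous decreasing delta
plot.  We treat this as a modelling choice of the package, not a claim about
any particular dataset.

### Calibration

The defaults in `sim_params()` were fixed once, by coarse grid search,
so that a simulated 43-participant session (five 60-trial blocks, balanced
colour x side combinations) lands inside the empirical bands typical of
left/right visual Simon tasks:

| quantity | default simulation | typical empirical range |
|---|---|---|
| mean saccade latency | ~335 ms | 250–350 ms |
| congruence effect (correct trials) | ~22 ms | 15–35 ms |
| overall accuracy difference | ~3.6 points | 3–8 points |
| bin-1 CAF depression (incongruent) | ~21 points | >= 15 points |
| CAF gap in bins 3–7 | < 3 points | < 5 points |
| delta plot | strictly decreasing | decreasing |

The load-bearing defaults are $\mu_c = 0.5$ evidence/ms, $A = 30$,
$\tau = 21.5$ ms, $b = 75$, $\sigma = 4/\sqrt{\mathrm{ms}}$, non-decision
time $200 \pm 35$ ms (floored at 50 ms), between-participant SDs of 0.03 on
drift and 25 ms on non-decision time.  Across 200 fresh replicate sessions
the aggregate delta decreased strictly from bin 1 to bin 7 in 96% of
sessions; the binding comparisons are bin 1 vs 2 (fast-error censoring, see
above) and bin 6 vs 7 (slow-tail noise), and this rate is a property of the
model family at these effect sizes rather than of any particular seed.

### Rendering

A trial is rendered as a 300-Hz horizontal gaze trace: fixation at 0 degrees
with Gaussian positional noise (default SD 0.05 degrees), then a saccade to
$\pm 12$ degrees starting exactly at the simulated latency, following a
minimum-jerk position profile with the main-sequence duration
$2.2 \cdot \text{amplitude} + 21$ ms, then fixation at the landing point.
Samples run from fixation onset (875–1250 ms before the target, in 125-ms
steps) to target offset at 1000 ms; target onset defines $t = 0$ and
rightward is positive.  The renderer deliberately omits blinks, drift,
glissades, vertical components and binocular disparity: passing detection
tests on these traces shows the detector recovers clean saccades through
realistic position noise, not that it would survive every artefact of a
real recording.

## Saccade detection

Velocity is estimated with a Savitzky–Golay first-derivative filter
(7 samples, cubic).  A cubic rather than quadratic kernel is used because at
300 Hz a quadratic 7-sample filter attenuates the ~475 deg/s peak of a
12-degree minimum-jerk saccade by almost 9%, while the cubic one tracks it
to a fraction of a percent; both are exposed in `detector_params()`.  Edge
samples use the one-sided fits from the same least-squares family, so the
series keeps its length.

The peak-velocity threshold is data-driven: starting at 100 deg/s, the
threshold is re-estimated as mean + 6 SD of the velocities below it until it
moves by less than 1 deg/s.  Candidate saccades are maximal runs of speed at
or above the converged threshold; runs closer than 20 ms are merged; each
run's onset and offset walk outward to the first sample below
mean + 3 SD of the trial's pre-target fixation noise, and the bracketing
sub-threshold samples are reported.  Two guards handle near-noiseless input:
the walk threshold is floored at 5% of the event's peak speed (otherwise the
filter's sub-threshold smear drags onsets outward on clean traces), and
events shorter than 10 ms are discarded.  On 1000 simulated trials at the
0.1-degree noise ceiling the detector recovers 100% of ground-truth saccade
onsets within two samples with no false positives on fixation-only traces.

## Response extraction and exclusions

The response is the first saccade after target onset with amplitude of at
least 2 degrees; smaller events are treated as fixational micro-movements
and skipped rather than voiding the trial.  A response is correct when its
direction matches the side instructed by the target's colour.  Exclusions
follow in two passes: first no-response trials and latencies below 100 ms
(anticipations, strict) or above 1000 ms (target offset, strict) — boundary
latencies are kept; then a single, non-iterated 3-SD rule per participant,
pooled over congruence, on the surviving trials.  Per-participant rather
than global SD matches the per-participant binning that follows; the rule's
scope and multiplier are arguments of `apply_exclusions()`.  On default
synthetic sessions about 1.4% of trials are removed — of the same order as,
though not identical to, what is reported for real recordings, which this
generator cannot and does not promise to reproduce exactly.

## Distributional statistics

Septile binning is stable rank binning: ties keep input order, and when the
trial count is not divisible by seven the larger bins are the earliest
(largest-remainder-first).  CAFs bin all included trials (errors retained)
per participant and condition; delta plots bin correct trials only,
separately per condition, pair the k-th bin means and place each delta at
the midpoint of the paired means.  Aggregation over participants is an
unweighted mean of per-participant values (vincentized averaging) in both
cases.  Each of these functions is tested against an independent brute-force
reimplementation (full sort + slice, plain loops) to $10^{-9}$ on random
data.

## Inference

Latency is analysed with a Gaussian linear mixed model
`rt_ms ~ congruence + (1 | participant)` (REML) on correct included trials;
accuracy, being binary, with a logistic mixed model of the same structure
(Laplace approximation); the CAF analysis adds a categorical bin factor and
its interaction (2 x 7); delta values are analysed with
`delta ~ bin + (1 | participant)`.  Estimation is delegated to `lme4`;
the package's own contract is the model specification, data marshalling,
contrast construction and adjustment.  F tests for the Gaussian models use
the inner-group residual denominator df, $N - n_{\text{participants}} - p$
(so a 43 x 7 delta table yields denominator 252); GLMM terms are tested with
Wald chi-square statistics.  Post hoc congruence contrasts within each bin
are z tests on the fitted log-odds scale, adjusted by the single-step
max-|z| method via `multcomp::glht`; the multivariate-normal quantile is
evaluated under a fixed internal seed so repeated calls agree, and
Holm–Bonferroni is the documented deterministic fallback if the joint
computation fails.  Where a simulated cohort is degenerate for some model
(for instance, no congruent errors at all, which is complete separation for
the logistic model), `run_pipeline()` downgrades that fit to `NULL` with a
warning instead of failing the run.

## Problem sizes used by the test suite

The packaged tests exercise the study scale the pipeline is designed for —
100 replicate sessions of 43 participants x 300 trials for the
distributional signature and calibration bands (replicate seeds 1–100,
fixed) — and smaller cohorts where the question is statistical rather than
distributional: 1000 rendered trials for detection recovery, 100 replicates
of 12 participants x 120 trials for latency-shift recovery, 15 x 150 for
log-odds recovery, and 10 x 140 for null error-rate control.  These sizes
are the package's choices; the properties they check are scale-free.

## Known limitations

The simulator is a calibration instrument, not a fitted model of any
dataset: its parameters were chosen to land in published effect-size bands,
so agreement with those bands validates the pipeline's bookkeeping, not the
model's truth.  Only horizontal saccades are simulated and analysed; blink
and artefact handling is out of scope; the detector's parameter values are
declared approximations of the cited algorithm family rather than a
reimplementation of any proprietary software; and exact F or z statistics
from real recordings are not reproducible from synthetic data and are not
targets.
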