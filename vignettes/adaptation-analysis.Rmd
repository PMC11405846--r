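---
title: "Separating sensory from motor adaptation during active whisker touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating sensory from motor adaptation during active whisker touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskadapt)
```

## The problem

During active sensing an animal controls its own stimulus: a mouse whisking
against a pole produces a sequence of touches whose strength, timing and
duration all vary from touch to touch. A drop in cortical firing across
that sequence is therefore ambiguous — it can reflect *sensory adaptation*
(neurons becoming less sensitive to touch of fixed strength) or *motor
adaptation* (the animal making mechanically weaker contacts), or both.
`whiskadapt` quantifies each contribution from three synchronous data
streams: 3D whisker-tracking solutions at 1 kHz, annotated touch events,
and sorted spike trains.

## Model and procedure

### Whisker geometry

Each whisker is a quadratic 3D Bezier curve defined by three control
points, the first at the whisker base. Its curvature is the closed form
$\kappa_{3D}(s) = |b'(s) \times b''(s)| / |b'(s)|^3$ (units 1/mm), the
reciprocal of the osculating-circle radius; for a quadratic curve $b''$ is
constant so the expression is exact and cheap. Touch strength is
$\Delta\kappa_{3D} = \kappa_{3D}(0) - \kappa_{3D,0}(0)$, the signed change
of base curvature relative to the contact-free resting state, averaged over
the half-open 5 ms window after touch onset (exactly 5 frames at 1 kHz).
$\Delta\kappa_{3D}$ is proportional to the bending moment at the follicle
up to an unknown stiffness constant, which is why the pipeline never
reports moments in absolute units. Base displacement $D_b$ (distance moved
by control point 0 between onset and onset + 5 ms) and base speed
$D_b/\Delta t$ summarise the motion component.

Assumptions worth keeping in mind: the quadratic Bezier is the tracker's
representation, not the whisker's true shape, so curvature is meaningful
mainly near the base where the fit is constrained; and the unsigned
curvature function makes $\Delta\kappa_{3D}$ signed only through the
subtraction (contact that straightens an intrinsically curved whisker gives
negative values). Full osculating-plane sign conventions are deliberately
not attempted.

### Touch sequences

Touch order within a trial (first, second, ...) pools all whiskers —
adaptation is assayed against the sequence of contacts the cortex saw, not
against per-whisker counts. Simultaneous onsets across whiskers are broken
by whisker label and flagged; overlapping touches of the *same* whisker are
rejected as tracking errors. Three order thresholds recur and are all
configurable: "later" touches are order ≥ 2 (first-vs-later dichotomies),
the adapted state for whisker-specific analyses is order ≥ 3, and
asymptotic-state summaries use order > 4.

### Responses and tuning curves

All responses are spike counts in half-open 30 ms windows from touch onset;
baselines use the 30 ms before onset. Units enter the analysis when their
post-touch count exceeds the pre-touch count under a one-sided paired
Wilcoxon signed-rank test at $\alpha = 0.05$ (counts are small integers,
so a rank test rather than a t test; at least 10 touches are required for
a determination). A session is analysed when it has at least 40 Go trials
and at least 2 touch-responsive units.

A tuning curve for one touch-order class is built by (1) discarding the
`ceiling(0.05 n)` touches of greatest $|\Delta\kappa_{3D}|$ as outliers
(ties broken by input position, removing later-indexed samples first, so
the rule is deterministic; below 20 samples nothing is removed), (2)
splitting the remainder into 4 equipopulated bins by sorted rank (bin
counts differ by at most 1, stable under duplicated values), and (3)
fitting an ordinary least-squares line through the 4 (bin mean strength,
bin mean count) points. Fitting on bin means rather than raw samples is the
canonical procedure here; raw-sample OLS is available via `bin_means =
FALSE`. If all strengths coincide the fit is degenerate: the slope is
undefined and the curve predicts the mean count, flagged as such.
Predictions are floored at 0 counts since the line can extrapolate below
zero. Sensory-adaptation analyses regress on $|\Delta\kappa_{3D}|$; signed
strengths remain available for direction-resolved curves.

When a predicted touch was part of the fit set, the curve is re-fitted
without it — including re-binning — before predicting (leave-one-out, one
touch at a time; `predict_loo()`). On noiseless linear data LOO and plain
predictions coincide, which the tests exploit.

### The attenuation decomposition

For a simultaneously recorded population the per-touch responses of all
units are summed ("population response") for robustness, and

$$\alpha = \frac{FR_1 - FR_1'}{FR_1 - FR_{later}}$$

where $FR_1$ and $FR_{later}$ are *median* observed population responses to
first and later touches and $FR_1'$ is the median of the later-touch tuning
curve evaluated at the first-touch strengths. Medians, not means, are used
for all three rates; the outlier filter applies to the tuning fit only, so
$FR_1$ and $FR_1'$ are computed over the same set of first touches and the
$\alpha = 0$ limit is exact. $\alpha$ is undefined (flagged `NA`) when
$FR_1 = FR_{later}$: with no attenuation there is nothing to decompose.
`later_min` defaults to 2; the alternative "later" definition (order > 4)
is a parameter, not a different code path.

### Whisker-specific adaptation

Eligible trials have their first two touches ("adapting") from one whisker,
a later (3rd-or-later) touch ("test") from the other, and no temporal
overlap (closed intervals) between the test touch and any touch of another
whisker. For each unit, the test whisker's adapted-state tuning curve is
fitted on that whisker's order ≥ 3 touches pooled from all trials of the
session — not only from eligible trials — excluding the test touches
themselves (the cross-validation step). The index
$I = (FR_{test} - FR_{pred})/(FR_{test} + FR_{pred})$ uses *means* over
test touches; it is antisymmetric and bounded in $[-1, 1]$ for non-negative
rates. Pooling the fit from all trials maximises the sample behind the
adapted-state curve; it is a divergence risk if adaptation differed
systematically between eligible and ineligible trials, which the synthetic
tests do not model.

### PSTH, latency and ROC

PSTHs are event-aligned mean rates in 1 ms bins; the 5 ms boxcar smoothing
option is label-preserving and for display only. Response latency is the
first 1 ms bin in (0, 30] ms whose rate exceeds the 30 ms pre-touch
baseline mean + 2 SD. This crossing rule is the least-constrained
convention in the package — no canonical definition exists for these data —
so it is isolated in `response_latency()` and reported with its threshold.
ROC discriminability compares touch-evoked counts with ongoing-activity
counts via the exact rank statistic $P(s > n) + \tfrac12 P(s = n)$
(identical multisets give exactly 0.5). Noise windows are deterministic:
they tile the interval from trial start to first touch (for first-touch
comparisons) and the gaps between a response window's end and the next
onset (for later touches), using every available non-overlapping window
rather than a random sample.

## The synthetic generator

`session_config()` / `generate_session()` draw a full session from one
seed: Go/NoGo trials; negative-binomial touches per trial with hit/miss
means 10.5 and 5 (SD 5.7 and 7.7); log-normal inter-touch onset intervals
(median 60 ms, floored at 40 ms — about one whisk cycle — and capped at
200 ms); log-normal touch durations clipped so same-whisker touches never
overlap; log-normal absolute strengths (median 0.03 /mm) with a
configurable multiplicative decay per touch order (`motor_decay`); and
units whose expected counts are `max(0, slope_k |dk| + intercept_k) +
baseline`, with the order-dependent multipliers implementing sensory
adaptation as a step schedule (unadapted at order 1, multiplied by
`intercept_ratio` / `slope_ratio` from `sa_onset_order` = 2 on). The
default intercept ratio is 0.32. With `whisker_specific = TRUE` the
schedule indexes each whisker's own touch count instead of the pooled
order. Counts are Poisson, or exactly equal to their expectation in
noiseless mode — the mode used for the exact limit-case checks, since
fractional counts cannot be represented as spike trains. Spike times are
rendered only in Poisson mode (uniform within the response window, plus
homogeneous baseline spikes).

`generate_bezier_frames()` renders frame tables whose closed-form base
curvature reproduces each touch's strength to machine precision, using the
layout $P_0 = B$, $P_1 = B + (d,0,0)$, $P_2 = B + (2d, 2d^2\kappa, 0)$ for
which $\kappa_{3D}(0) = h/(2d^2)$ exactly, on top of sinusoidal (~12 Hz)
base motion. `implied_alpha()` gives the decomposition's closed-form value
under the model: per-order expected strengths and counts, order weights
from the touch-count survival function, and a weighted least-squares line
through the per-order expectation points standing in for the pooled
later-touch fit. The two limit cases are exact (identical tuning ⇒ 0;
stationary strengths ⇒ 1); in mixed cases the closed form ignores
within-order strength variance, so estimator and implied value are only
expected to agree to about ±0.1 — the same band used for Poisson recovery.

What the generator does *not* emulate: whisker biophysics (resonance,
friction), bursting or refractory spike statistics, rate co-fluctuations
across units (arousal), decision-dependent touch statistics, and tracking
noise in the control points. Passing recovery tests therefore show the
*estimators* are consistent under the assumed linear-Poisson model, not
that real sessions satisfy that model.

## Numerical choices and degenerate inputs

* Half-open windows everywhere (`[t, t+30)`), so adjacent windows
  partition time and a spike on a boundary is counted once.
* Degenerate Bezier tangents (zero speed) report curvature 0 with a
  warning — they arise only from pathological tracking output.
* Resting curvature is the per-whisker per-trial *median* over
  contact-free frames, robust to occasional tracking noise; nothing in the
  data dictates a specific estimator, so the median is a package choice.
* Tie-breaks (outlier filter, binning, simultaneous onsets) are all
  deterministic and documented at the function level; reports are
  byte-identical across reruns, and `summary.json` carries a provenance
  block (config hash, seed, package version).
* `touches_sd^2 > touches_mean` is enforced at configuration time (the
  negative binomial requires over-dispersion).

## Problem sizes

The shipped tests run sessions of 40–300 trials for behavioural and
geometric checks, noiseless 60–200-trial sessions for the exact limit
cases, and a 10-seed × 500-trial Poisson experiment for parameter
recovery (intercept-ratio error and $\alpha$ error both within ±0.1 of
their injected/implied values). These sizes were chosen so each property
is measured well inside its tolerance; the generator scales to larger
sessions linearly in touches × units.

## Known limitations

* The latency rule and the rest-curvature estimator are conventions, not
  field standards; both are isolated behind single functions.
* `implied_alpha()` is approximate away from its two limit cases (see
  above).
* The whisker-specific analysis assumes exactly two candidate whiskers;
  three-whisker generalisations would need a definition of "the other
  whisker".
* Ingestion is CSV-schema based; no reader for any specific acquisition
  system's native format is provided.
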