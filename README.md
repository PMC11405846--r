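# whiskadapt

Sensory vs motor adaptation analysis for active whisker touch.

When a head-fixed mouse repeatedly palpates an object with its whiskers,
cortical responses in barrel cortex shrink over the course of the touch
sequence. Two very different mechanisms can produce that attenuation:

* **motor adaptation** — the animal makes progressively weaker contacts, so
  later touches simply carry less mechanical drive; and
* **sensory adaptation (SA)** — neurons become less sensitive to a touch of
  the *same* strength as the sequence progresses.

`whiskadapt` implements an analysis pipeline that disentangles the two from
simultaneous 3D whisker tracking and extracellular recordings, plus a seeded
synthetic-session generator with known ground truth so every stage can be
validated end to end. It is aimed at systems neuroscientists working with
tracked whisker video (Bezier tracking solutions), touch-event tables and
sorted spike trains.

## The quantities at the core

**Touch strength.** A tracked whisker is a quadratic 3D Bezier curve
`b(s) = (1-s)^2 P0 + 2s(1-s) P1 + s^2 P2`. Its bending is the closed-form
curvature

```
kappa_3D(s) = |b'(s) x b''(s)| / |b'(s)|^3        [1/mm]
```

and the strength of a touch is the curvature change at the whisker base
relative to rest, `delta kappa_3D = kappa_3D(0) - kappa_3D,0(0)`, averaged
over the 5 ms after touch onset. Up to an unknown stiffness factor this is
proportional to the bending moment driving the mechanoreceptors.

**Tuning curves.** For each touch-order class (first touch in a trial,
second, "later", ...), spike counts in the 30 ms window from touch onset are
regressed on touch strength: the strongest 5% of touches are discarded, the
rest discretised into 4 equipopulated bins, and a line fitted through the 4
bin means.

**The attenuation decomposition.** With `FR_1` and `FR_later` the median
population responses to first and later touches, and `FR_1'` the median
first-touch response *predicted* by the later-touch tuning curve
(i.e. at first-touch strengths but with adapted sensitivity),

```
alpha = (FR_1 - FR_1') / (FR_1 - FR_later)
```

is 0 when the attenuation is purely motor (tuning unchanged) and 1 when it
is purely sensory (strength unchanged).

**Whisker specificity.** For trials whose first two ("adapting") touches
come from one whisker and a later ("test") touch from the other, the index

```
I = (FR_test - FR_predicted) / (FR_test + FR_predicted)
```

is positive when the test whisker responds above its own adapted-state
prediction — adaptation did not transfer across whiskers — and zero when
adaptation is shared.

## Worked example

```r
library(whiskadapt)

cfg  <- session_config(n_trials = 300, intercept_ratio = 0.32,
                       motor_decay = 0.85, seed = 42)
sess <- generate_session(cfg)
sess
#> <synthetic_session> 300 trials, 1320 touches, 8 units, noise = poisson

pop <- population_response(sess$counts)
res <- attenuation_decomposition(pop)
res
#> <alpha_result> FR1 40, FR_later 15, FR1' 31.64 -> alpha 0.3342
implied_alpha(cfg)
#> [1] 0.3403562
```

The generated session mixes a motor effect (touch strength decays by 15%
per touch) with a sensory effect (tuning intercept drops to 0.32 of its
first-touch value from the second touch on). The median population response
falls from 40 to 15 spikes per 30 ms window; feeding first-touch strengths
through the later-touch tuning curve predicts 31.6, so about a third of the
attenuation (alpha = 0.33) is attributable to changed sensitivity — close
to the value the generative model implies (0.34). The per-order tuning
curves themselves:

```r
fit_tuning_curve(pop[pop$order == 1, ], strength = "abs_strength",
                 count = "pop_count", order_label = "1")
#> <tuning_curve> order 1: slope 732.1, intercept 16.25, n = 143
res$tuning_later
#> <tuning_curve> order later>=2: slope 779.7, intercept 4.881, n = 1110
```

show the signature of sensory adaptation: a similar slope but a much lower
intercept for later touches. Making the injected adaptation whisker-specific
turns the WSA index positive for every unit:

```r
cfgw <- session_config(n_trials = 300, intercept_ratio = 0.32,
                       motor_decay = 0.85, whisker_specific = TRUE, seed = 42)
w <- wsa_analysis(generate_session(cfgw)$counts)
mean(w$index_i > 0); round(mean(w$index_i), 3)
#> [1] 1
#> [1] 0.111
```

`run_pipeline()` chains all of the above (plus unit screening, touch
statistics, PSTH/latency and ROC discriminability tables) over a session
directory of `trials.csv` / `touches.csv` / `spikes.csv` and writes CSV
reports with a provenance-stamped `summary.json`; see
`vignette sources under vignettes/` for the full account of the method and
its parameters.

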