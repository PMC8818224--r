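---
title: "Categorising collar-accelerometer behaviour: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorising collar-accelerometer behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcat)
library(dplyr)
```

## The problem

Collar-mounted tri-axial accelerometers record an animal's acceleration
along three orthogonal axes — heave (vertical), surge (longitudinal,
head-to-tail), and sway (transverse). Because the signal mixes gravity
(posture) with body movement (gait, intensity), a well-chosen set of
derived channels lets a classifier recover what the animal was doing at
each logging event. `accelcat` implements this workflow end to end for a
large-felid ethogram: a ground-truthed signal simulator with configurable
logger profiles, rail-reference mounting calibration, the fourteen standard
per-sample predictors, a three-resolution behaviour hierarchy, and
random-forest classifiers with a validation-based early-stopping protocol,
plus the evaluation and device-comparison statistics.

The package's numerical experiments run entirely on simulated sessions:
real deployments enter only through two small published reference tables
(per-behaviour event counts and per-behaviour accuracies for a CEFAS-class
and a GCDC-class logger) used by the arithmetic reproduced in
`scripts/acceptance.R`.

## Signal model

Each behaviour is described by a `behaviour_spec()`:

* **Posture** — a unit gravity direction in device axes. Standing puts
  1 g in heave; a head-down stalk rotates gravity toward surge; lying on
  the side rotates it toward sway.
* **Movement intensity** — `dynamic_amplitude`, the RMS (in g) of the
  dynamic heave component after synthesis.
* **Gait** — a stride rate (strides/s) and a footfall pattern: for each
  limb a contact onset phase, a contact duration (fractions of one stride
  cycle), and a relative weight. Walk is a four-beat sequential pattern,
  trot a two-beat diagonal pattern, canter a three-beat 1-2-1 pattern, and
  gallop a four-beat pattern with suspension phases.

A simulated segment is

> gravity projected onto the posture + footfall-locked raised-cosine
> impulses (heave, with smaller surge/sway components whose signs
> alternate with limb side and fore/hind position) + a sinusoidal
> centre-of-mass oscillation at the stride rate + i.i.d. Gaussian sensor
> noise per axis.

The stride-rate body oscillation deserves a note. A pure impulse-train
model concentrates spectral energy at the *beat* frequency (two to four
times the stride rate for symmetric gaits), which would make the
fundamental hard to find in a periodogram. Quadrupeds, however, bounce
their centre of mass once per stride (and the gallop adds trunk flexion at
the same frequency), so the model includes a per-gait `body_bounce` term.
With it, the dominant spectral line of every gait sits at its stride rate
while the footfall harmonics still make the gaits spectrally distinct:

```{r spectra}
specs <- cheetah_behaviours()
for (b in c("walk", "trot", "canter", "gallop")) {
  seg <- simulate_segment(b, 10, rate = 100, noise_sd = 0, seed = 1)
  x <- seg$heave_g - mean(seg$heave_g)
  sp <- Mod(fft(x))[2:500]
  fr <- (1:499) / 10
  cat(sprintf("%-8s stride %.1f /s, dominant peak %.1f Hz\n",
              b, specs[[b]]$stride_rate, fr[which.max(sp)]))
}
```

Stride rates (walk 1.0, trot 1.8, canter 2.2, gallop 2.8 strides/s) and
amplitudes (lie 0.02 g RMS up to gallop 2.2 g RMS) are package
assumptions chosen to be plausible for a large cursorial felid — they are
stated as assumptions, not measurements. Amplitudes are ordered
lie < stand < walk < trot < canter < gallop so intermediate gaits remain
genuinely confusable, and the gallop's amplitude is large enough to
saturate a ±2.3 g logger, which is exactly the regime in which a
lower-capacity device loses information during high-intensity pursuit.

Sessions (`compose_session()`) emulate a lure-chase exercise bout: a
leading rail-reference window (collar hanging on a rail, gravity along
+heave, no body movement, labelled "unassignable"), then 10–15 minutes of
three or four chases punctuated by rest periods. A mounting-offset
rotation applied to the whole trace simulates a non-centred device. The
default `cheetah_session_plan("full")` touches all 17 fine behaviours with
a realistic imbalance (lying dominates; pounce and sitting stalk are
rare); `"small"` is a 2-minute cut used by the test suite.

## Device profiles

`apply_device()` turns the ideal 100-samples/s ground truth into what a
logger records: linear-interpolation resampling onto the device grid,
symmetric clipping at `max_accel`, and rounding to the amplitude
resolution when one is specified. The two built-in profiles are a
30 Hz / ±2.3 g (continuous) device and a 50 Hz / ±8.6 g / 0.001 g
device. Generating one ideal trace and recording it through both profiles
mirrors a dual-logger collar: both devices see the same ground truth.
Resampling is linear interpolation rather than decimation — the simplest
convention that a test oracle can reproduce exactly.

## Calibration

The calibration corrects for non-centred mounting using the rail window:
the mean acceleration over that window is pure gravity in a known
direction, so the minimal (axis-angle) rotation taking the window mean
onto the expected direction is applied to every sample. Only a rotation is
fitted — both modelled loggers already report in calibrated g, so no
per-axis gain or offset is estimated. Simulation shows planted offsets up
to 60° recovered to well under 2° at 0.05 g sensor noise; magnitudes are
preserved to machine precision by construction.

## The fourteen predictors

Per logging event: raw `heave`, `surge`, `sway`; `static_*` per axis (a
2-second centred rolling mean — centred rather than trailing to avoid
phase lag, with shrinking windows at the edges; even window lengths extend
one sample further forward); `dynamic_*` per axis (`|raw − static|`,
deliberately unsigned); `vedba` and `vesba` (Euclidean norms of the
dynamic and static vectors); `anim_stat`; `pitch`; `roll`.

Angle conventions: `pitch = asin(static_surge / VeSBA)` and
`roll = asin(static_sway / VeSBA)`, in degrees, so an upright stance gives
0° and a head-to-the-ground posture pitches to +90°. `anim_stat` is
defined here as the postural deviation angle — the angle between the
static vector and the calibrated resting orientation (+heave by default):
0° at rest posture, 90° orthogonal to it. These are declared package
conventions: `pitch`/`roll` definitions vary across the biologging
literature and `anim_stat` has no single standard formula, so all three
are isolated behind one operation each and validated against closed-form
oracles in the test suite.

Degenerate inputs are errors, not silent NAs: a zero static vector makes
the angle channels undefined, a trace shorter than one rolling window
cannot be featurised, and empty signals are refused.

## Ethogram and label operations

Labels are exchanged as half-open intervals `[start, end)`; a sample on a
boundary belongs to the later behaviour. Samples not covered by any
interval (and the rail window) are "unassignable" and removed before
modelling, with the removed count reported.

The hierarchy ships as a three-column CSV (`fine,medium,coarse`). Fine has
17 classes; medium collapses the four sedentary postures to "sedentary"
and the two moving stalks to "moving stalk", and sends "pounce" to
"other" (it cannot be categorised reliably at that level); coarse keeps
"active" (gaits, moving stalks, pounce), "inactive" (postures and
sedentary stalks), "head movement", and "other". Collapsing is total,
conserves counts, and is idempotent by level — all asserted at
construction and in tests. Collapsing the published per-device fine event
counts reproduces the published sedentary / moving-stalk / active /
inactive aggregates exactly; this arithmetic is one of the package's
acceptance checks.

## Classifier protocol

* **Split**: 60% train / 20% validation / 20% test, uniformly at random
  per logging event, seeded; train receives `floor(0.6 n)` rows,
  validation `floor(0.2 n)`, test the remainder.
* **Early stopping**: the forest grows two trees at a time; after each
  increment the cumulative forest's validation overall accuracy is
  recorded, and growth stops when the mean of the last two evaluations
  improves on the mean of the previous two by less than 0.001 (0.1
  percentage points), or at 500 trees. Class votes are accumulated across
  increments, so probabilities are vote fractions and predictions are
  deterministic (ties to the first class level).
* **Depth refinement**: one early-stopped forest per depth in the grid
  (default 6, 12, 24; depth d caps trees at 2^d terminal nodes); the
  model with the highest validation accuracy is retained, ties to the
  smallest depth.
* **Cross-validation**: seeded five-fold, fold sizes within one row of
  each other, mean ± sd per metric.
* **Metrics**: overall accuracy is correct/total. Multiclass MSE is the
  mean of `(1 − p_truth)^2` over events (the squared probability
  shortfall on the true class), RMSE its square root, and
  `r² = 1 − MSE / var(numeric class codes)` — the conventions of the
  H2O-style random-forest tooling this protocol models, kept so metric
  tables are comparable in form.
* **Class imbalance** is left uncorrected: rare behaviours (pounce,
  sitting stalk) stay rare in training, which is part of what the
  experiment measures.
* **"Other"** stays in training and prediction; it is excluded only when
  reporting headline accuracy (rows whose *true* label is "other" leave
  both numerator and denominator).

Importance is the impurity (Gini) improvement, reported raw, scaled (% of
the top predictor, so the maximum is exactly 100) and as explanatory
power (% of the total, summing to 100).

## Evaluation and device comparison

Per-behaviour accuracy is per-class recall (diagonal over row total) — the
only reading consistent with row-normalised confusion matrices.
Misclassification shares default to the full row count as denominator
(shares of the behaviour's events), with `denominator = "errors"`
available, because published usage is ambiguous between the two.

Device comparisons are computed on the validation partition. For each
behaviour the 2×2 device-by-correct/incorrect table is tested with
Pearson's chi-squared (df = 1, no continuity correction), falling back to
Fisher's exact test — odds ratio in lieu of the statistic — when any
expected cell is below 5 (this is what happens for very rare behaviours).
Significance is two-sided at 0.05 with no multiple-testing correction; the
verdict names the better device or "n.d.". The mean difference averages
the per-behaviour percent differences, excluding "other".

## The full experiment

```{r experiment, eval = FALSE}
report <- run_experiment(experiment_config(seed = 1))
report$metrics
report$mean_differences
autoplot(report)
```

`run_experiment()` fits 2 devices × 3 resolutions = 6 models on one
simulated session and produces the per-behaviour accuracy table, the
comparison tables, and a structural check that collapsing the fine model's
predictions with the coarse map never loses accuracy (a counting
argument: merging classes can only turn errors into hits). One master
seed fans out as session = seed, split = seed + 1, trees = seed + 2, so
runs are reproducible end to end and stages can be re-run independently.

Problem sizes: the default full session is ~12 minutes (≈ 721 s including
the rail window), i.e. ≈ 21,600 CEFAS and ≈ 36,000 GCDC logging events;
the test suite uses the 2-minute plan. These sizes were chosen so a
complete six-model experiment with depth search runs in well under a
minute on a single core while every behaviour class is still represented
in all three partitions with high probability.

## What the simulator does and does not show

Passing tests on simulated sessions demonstrate that the pipeline's
mechanics are correct — calibration recovers planted rotations, features
match their definitions, the classifier protocol is implemented as stated,
the evaluation arithmetic is exact, and the device comparison behaves
sensibly under clipping. They do *not* demonstrate field performance: the
simulator's classes are cleaner than real cheetah data (no transitional
movements, no collar slip after calibration, no autocorrelated sensor
drift, no individual variation between animals), so synthetic accuracies
(≈ 99% at coarse resolution) exceed what real deployments report
(≈ 83–90%). Real-data claims should rest on the published reference
tables, which the package reproduces arithmetically, not on the
simulator's classification scores. Per-sample random splitting also means
validation rows are temporally adjacent to training rows; with strongly
autocorrelated signals this flatters accuracy relative to
leave-one-session-out evaluation, a caveat shared by per-event protocols
generally.

## Known limitations

* No gyroscope, magnetometer, or GPS channels; no windowed summary
  features (each logging event is classified on its own).
* The gait dynamics are statistical, not biomechanically calibrated.
* Calibration assumes the rail window is truly static and gravity-only.
* The forest implementation models the early-stopping protocol with
  2-tree increments exactly; stopping on a noisy validation accuracy can
  halt small forests early on easy problems (by design — it is the stated
  protocol).
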