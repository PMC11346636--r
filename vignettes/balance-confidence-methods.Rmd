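---
title: "Methods: classifying balance confidence from smartphone gait signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying balance confidence from smartphone gait signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitconf)
```

## The problem

People with a lower limb amputation often walk with increased gait
variability and instability, and their *balance confidence* — measured
clinically with the 16-item Activities-specific Balance Confidence (ABC)
questionnaire, scored as the mean of the items on a 0–100% scale — can be
mismatched with their actual balance ability. Scores of 80% or more are
conventionally read as high confidence. `gaitconf` implements a pipeline
that classifies a walker into the high- or low-confidence group using only
inertial signals recorded by a smartphone worn at the posterior pelvis
during a six-minute walk test (6MWT): signal conditioning, foot-strike
event cleanup, a 62-feature-per-step gait feature scheme aggregated to 248
trial features, correlation-based feature selection, and a random forest
evaluated with participant-level leave-one-out cross-validation (LOOCV).

Because no clinical recordings ship with the package, a synthetic 6MWT
generator with analytic ground truth is a first-class module: every stage
is validated against signals whose true foot strikes, cadence, and class
structure are known by construction.

## Signal conditioning

Smartphone logging has a variable sample clock near 50 Hz, so each channel
(three body-frame accelerations ML/AP/Vert, three orientation angles
tilt/rotation/obliquity) is linearly interpolated onto the fixed grid
`t_k = t_0 + k/50` for `k = 0 … floor((t_last − t_0)·50)`. The grid is
anchored at the first timestamp and never extends past the last one: no
data are invented outside the recording. Device axes map to body axes
through a configurable `axis_map`; the default assumes a portrait phone at
the posterior pelvis (device y vertical, x medio-lateral, z
anterior-posterior; pitch→tilt, azimuth→rotation, roll→obliquity). The
paper-trail format of the source app is not public, so the package defines
its own plain CSV schema
(`time_s,ax,ay,az,gx,gy,gz,azimuth_deg,pitch_deg,roll_deg`) and treats it
as canonical.

Signals are then low-pass filtered with a fourth-order Butterworth filter
(4 Hz cutoff) applied forward and backward, giving zero net phase and the
squared magnitude response `1/(1 + (f/4)^8)` at 50 Hz. Gait energy below
4 Hz passes essentially unchanged (a 1 Hz tone keeps ≥ 99.9% of its
amplitude) while sensor noise above it is crushed (a 10 Hz tone keeps
< 0.1%). Edges are handled by odd-reflection padding of three times the
filter's *effective impulse length*, computed from the largest pole radius
as the point where the impulse response has decayed below 1e−12 (~110
samples here, so ~330 samples of padding). A fixed short pad proportional
only to the filter order would leave startup transients orders of
magnitude above the 1e−9 accuracy this stage promises for DC gain and
phase; tying the pad to the measured pole decay makes those contracts hold
for any stable configuration. Gravity is deliberately *not* removed: the
feature scheme operates on filtered raw accelerations, and no orientation
re-estimation or sensor fusion is attempted.

## Foot-strike cleanup

A foot strike coincides with a peak of the anterior-posterior (AP)
acceleration. The package ships a baseline candidate detector — prominent
local AP maxima, with prominence at least `0.3 × SD(AP)` — as a stand-in
for an external learned step detector, and accepts externally supplied
candidates through the same cleanup path. All cleanup heuristics reason
about *prominent* AP maxima ("apexes") rather than every ripple, so
low-amplitude noise wiggles cannot anchor a strike.

Two post-processing rules correct typical prediction errors:

* **Extra predictions.** Candidates are grouped by their nearest apex;
  within each group only the candidate closest to the apex survives, with
  equidistant ties resolved toward the earlier candidate (deterministic and
  order-stable). Grouping by nearest apex, rather than by "no apex strictly
  between", is what makes the canonical case work: two predictions
  flanking one apex form a single group even though the apex lies between
  them.
* **Missed steps.** A gap is flagged when an inter-strike duration is at
  least 1.5× the *immediately preceding* inter-strike duration (the
  simplest reading of "the previous pair of steps"; the factor is
  configurable). Inside a flagged gap, and outside an adaptive locking
  period `L = 0.5 × median inter-strike duration` around the flanking
  strikes, the largest apex is inserted as a strike; if the window holds no
  apex, nothing is inserted — absence of an AP peak is absence of evidence.
  Passes repeat, durations recomputed, until no gap is flagged (bounded by
  `max_insert_passes`).

`clean_footstrikes()` composes removal, insertion, and a final enforcement
of the locking period as a minimum separation (the lower-AP strike of any
too-close pair is dropped). The composition is idempotent, never reorders
indices, and on noise-free periodic gait reproduces the ground truth at
the exact sample index.

## The feature scheme

Steps span consecutive foot strikes as half-open sample windows; sides
alternate strictly, seeded by the sign of the mean ML acceleration in the
first window (a single pelvis sensor cannot observe side directly, so
alternation is the only structural constraint; the seed heuristic is
overridable). Each step yields 62 features:

* **Temporal (5):** cadence `60/step-time`; the most recent right and left
  step times; stride time (interval back to the previous ipsilateral
  strike); and the step-time symmetry index `|R − L| / (0.5(R + L)) × 100`.
  The earliest windows lack contralateral or ipsilateral context and carry
  `NA` there rather than fabricated values; aggregation skips them.
* **Descriptive (27):** min/max of the three accelerations, mean/SD/RMS of
  all six channels, and range of the three orientation angles.
* **Frequency-domain (30):** per channel, from the one-sided amplitude
  spectrum of the mean-removed window zero-padded to 128 samples (uniform
  bin resolution across variable-length steps): the quartile frequency
  (lowest frequency at which cumulative power reaches 25% of the total),
  the maximum amplitude, the SD of amplitudes, peak distinction
  `(max − mean)/mean`, and REOH, the ratio of even- to odd-harmonic energy
  at multiples (1–10) of the step fundamental `1/window-duration`. REOH is
  computed from the *unpadded* window's DFT evaluated exactly at the
  harmonic bins: zero-padding smears an integer-cycle component across
  neighbouring bins, which would leak spurious energy into the opposite
  parity and destroy the defining property that a pure tone at the
  fundamental gives REOH ≈ 0 while a tone at twice the fundamental sends it
  to the epsilon-guarded ceiling.

Windows shorter than 8 samples return `NA` spectral features. Per trial,
each of the 62 features is aggregated over all steps with min, max, mean,
and SD — 248 features named `<base>__<stat>` — plus a step count carried
separately. Spectral features are computed per step window (the same unit
as every other feature), and cadence is the instantaneous `60/step-time`.

## Selection and classification

Participants are labelled from their ABC score with the inclusive 80%
threshold. Correlation-based feature selection (CFS) scores a subset `S`
of `k` features by the merit
`k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)`, with `r̄_cf` the mean absolute
point-biserial feature–class correlation and `r̄_ff` the mean absolute
pairwise feature–feature correlation. Correlations are Pearson on the
continuous features — deterministic and discretization-free; the merit
function is the pluggable part if a symmetrical-uncertainty variant is
ever wanted. The search is forward best-first from the empty set, stopping
after five consecutive expansions that fail to improve the best merit; it
is deterministic given column order, and on problems small enough to
enumerate it returns the exhaustive optimum. Zero-variance features are
treated as uncorrelated and logged.

The classifier is a 100-tree random forest with `floor(log2 p) + 1`
candidate features per split, bootstrap samples of size *n*, and unlimited
depth — the conventions of the desktop tool family this pipeline mirrors,
which names no hyperparameters of record. Exact vote ties go to *low*
confidence, the clinically conservative call (a false "low" costs a
follow-up questionnaire; a false "high" misses a person who may need
intervention). Self-reported fall history is carried as cohort metadata
only and never enters the feature matrix.

Evaluation is participant-level LOOCV: one model per held-out participant,
confusion counts accumulated over all folds, metrics (accuracy,
sensitivity, specificity, precision; positive class = high confidence)
reported in percent to one decimal. Feature selection runs in one of two
modes: `global` (CFS once on the full cohort before cross-validation,
matching the single reported selection outcome of the study design this
mirrors) and `nested` (CFS refit inside every training fold). Global
selection lets the held-out participant influence which features are
available to the fold, so its LOOCV estimate is optimistic whenever
selection can overfit; the package's own end-to-end validation therefore
uses the nested mode, and on a null cohort (identical gait in both
classes) the global mode would measure selection leakage rather than
signal. Both modes are exposed; the default of `run_pipeline()` is
`global` for fidelity to the mirrored design, and the choice is echoed in
every report.

## The synthetic 6MWT generator

The generator produces the statistical structure the pipeline consumes,
not biomechanics: foot strikes are an alternating-side renewal process
(mean step time `60/cadence`, per-side means split by an asymmetry
fraction, lognormal jitter with a configurable CV), and signals are
harmonics plus strike-locked pulses. Vertical acceleration oscillates at
step frequency on top of gravity; AP acceleration carries a Gaussian pulse
(SD 0.05 s) at each strike plus a small step-frequency harmonic; ML sway
oscillates at stride frequency with sign alternating by stance side;
orientation angles are smooth stride-frequency sinusoids. All oscillatory
terms are phased by the *gait cycle itself* — the continuous step count
interpolated between the jittered strike times — because a wall-clock
phase decorrelates from a renewal process as drift accumulates and ends up
planting harmonic peaks mid-gap where the cleanup stage would rightly
read them as steps. White noise (default SD 0.15 m/s²) is added to the
accelerations, and the sample clock is lognormal around 20 ms (default
10% CV), emulating variable smartphone sampling near 50 Hz.

The default six-minute trial at cadence 100 yields 600 strikes; in the
zero-jitter limit the strike count is exactly `duration·cadence/60` and
every stage of the pipeline recovers the truth exactly. Cohorts draw
per-trial seeds from a single cohort seed, so every fixture is
reproducible bit for bit. The default class-conditional parameters encode
the expected direction of impairment — the low-confidence class at cadence
88 vs 105, step-time CV 0.09 vs 0.04, asymmetry 0.12 vs 0.04, ML sway 1.5
vs 0.8 m/s² — magnitudes chosen as plausible for prosthetic gait, not as
claims about any cohort. ABC scores are drawn uniformly above/below the
80% threshold consistently with the class.

What the generator does *not* model bounds what green tests mean: there
are no turns at hallway ends, no fatigue drift, no prosthetic-specific
asymmetries beyond a scalar step-time split, no gravity-direction changes,
and the noise is white rather than structured. Passing tests show the
pipeline's logic is correct under the statistical regime it assumes;
they do not certify performance on clinical recordings.

## Numerical choices and degenerate inputs

* Resampled length is `floor((t_last − t_0)·rate + 1e−9) + 1`; the small
  epsilon keeps grids that land exactly on the final timestamp from losing
  a sample to floating-point rounding.
* Strike ties: equidistant extra-prediction candidates keep the earlier
  one; equal-height separation conflicts keep the earlier strike; apex
  assignment ties go to the earlier apex. All ties are deterministic.
* A flat AP channel yields an empty candidate series (not an error);
  fewer than 3 strikes skip insertion with a warning; fewer than 4 strikes
  make segmentation an error naming the trial.
* REOH denominators are guarded by machine epsilon; harmonics above the
  window's Nyquist index are dropped for very short windows.
* CFS merit improvements below 1e−12 do not count as improvements, keeping
  the search stable under floating-point noise.
* Forest fold seeds are `seed + fold index`, making every fold and hence
  every report reproducible from one integer.

## Validation scale

The package's own end-to-end checks run two 40-participant cohorts of
full six-minute trials (a class-separated one and a null one, seed 7) —
about 1.5 minutes of compute — alongside property suites on shorter
trials. The separated cohort must beat the majority-class baseline by at
least 10 percentage points under nested-selection LOOCV; the null cohort
must stay within 10 points of its baseline. At these defaults the
separated cohort classifies perfectly and the null cohort sits at chance,
which is exactly the pair of outcomes that shows the pipeline finds real
structure and does not invent absent structure.

## Known limitations

* The baseline AP-peak detector is a stand-in for a learned step
  detector; on real signals with blunted or double AP peaks it will need
  externally supplied candidates (supported via `source = "external"`).
* Side assignment is a heuristic; true left/right identity is
  unobservable from a single pelvis sensor without additional modelling.
* The 80% ABC threshold was validated for older adults, not specifically
  for prosthesis users; it is a configurable parameter.
* Global-selection LOOCV estimates are optimistic by construction; use
  the nested mode when an unbiased generalization estimate matters.
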