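---
title: "Evaluating accelerometer placement for activity recognition and energy expenditure"
author: "placewear developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating accelerometer placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placewear)
```

## The problem

Wearable accelerometers are the workhorse of free-living physical-activity
measurement, but studies disagree on where to wear them: wrist devices are
convenient and popular, hip devices are the historical standard, and ankle,
thigh and upper-arm placements each have advocates. `placewear` provides a
complete, seeded testbed for the question: given recordings from five
placements (ankle, upper arm, hip, thigh, wrist) during scripted activities
of daily life, how does each of the 31 possible placement combinations
perform at (i) recognizing activity categories — sedentary, locomotion,
lifestyle — and individual activities, and (ii) estimating energy
expenditure in metabolic equivalents (METs, 1 MET = 3.5 mL O₂·min⁻¹·kg⁻¹)?

Because raw laboratory recordings of this kind are rarely shareable, the
package ships a first-class synthetic-data generator with the statistical
structure the analysis assumes, so the entire pipeline is testable
end to end without any external data.

## The pipeline

### Windowed features

Signals are segmented into contiguous 16-second windows (non-overlapping by
default; an overlap fraction is configurable). Each window yields 15
features of the vector magnitude VM and the raw axes: mean and SD of VM;
mean and SD of the per-sample angle between the x-axis and the VM; lag-1
autocovariance of VM; skewness; excess kurtosis; entropy; the coefficient of
variation `100·sd/mean`; the three pairwise axis correlations; the fraction
of spectral modulus in the 0.6-2.5 Hz band (the human locomotion band); the
dominant frequency; and the modulus fraction at the dominant frequency.

Numerical conventions, chosen once and exposed as configuration:

* **Angle**: `acos(x / VM)` in radians. The angle feature is sometimes
  described relative to "vertical on the device"; since verticality is
  orientation-dependent anyway, the literal axis-vs-VM definition is
  implemented and the axis is configurable. Samples with `VM = 0` are
  skipped (and logged); an all-zero window flags the angle and CV features.
* **"Covariance of the VM"**: implemented as the lag-1 sample
  autocovariance. Plain variance would duplicate the SD feature squared;
  lag-1 autocovariance adds temporal-smoothness information. A `variance`
  mode is available.
* **Kurtosis** is excess kurtosis (normal → 0). **Entropy** uses a 20-bin
  equal-width histogram over the window's VM range, in bits, with
  `0·log 0 ≡ 0`; a constant window has entropy 0.
* **Spectrum**: the VM is mean-removed before the FFT, which removes the DC
  bin exactly — otherwise the dominant frequency would trivially be 0 for
  any signal with nonzero mean. Moduli (not squared moduli) are summed,
  following the feature's standard wording. Dominant-frequency ties break
  toward the lowest frequency, so output is deterministic. A constant
  window reports 0/0/0 with a degeneracy flag.
* Zero-variance axes make Pearson correlations undefined; they are reported
  as 0 with a warning rather than `NaN`, since a flat axis carries no
  co-movement evidence either way.

Features are not standardized before modeling: random forests are invariant
to monotone feature scaling.

### MET labels

Breath-by-breath VO2 is smoothed with a 30-second running average. Because
breath intervals are irregular, the smoother is time-based (all breaths
within ±15 s), not breath-count-based. Steady state is taken as everything
after a fixed 120-s onset — the plateau in VO2 typically establishes about
two minutes into a constant-intensity activity — replacing manual plateau
inspection with a deterministic rule; an optional slope test can reject
windows that still trend. The session MET is the plateau mean divided by
3.5, and is assigned to every window of that session (per-window calorimetry
does not exist even in principle at this protocol's resolution). Traces
ending before the onset raise a counted exclusion, mirroring the exclusion
of sessions that never reach a steady-state metabolic rate.

### Experiment design

All 31 non-empty subsets of the five placements are enumerated (letter codes
A-E in the fixed order ankle, upper arm, hip, thigh, wrist). Five tasks are
defined: three binary category tasks scored by balanced accuracy (the mean
of sensitivity and specificity, robust to the heavy class imbalance —
sedentary windows are a small minority), individual-activity recognition
scored by accuracy against a `100/k`% chance level (3.1% for 32 classes),
and MET regression scored by RMSE.

Cross-validation is participant-exclusive and nested: outer folds hold out
one-sixth of participants for testing (6 folds by default — the number is
implied by the one-sixth rule and is configurable); the remaining
development participants are split 4/5-1/5 into five inner folds for
hyperparameter tuning. Tuning maximizes (or minimizes, for RMSE) the mean
inner-validation metric over a small standard grid — 300 trees,
`mtry ∈ {√p, p/3}`, minimum leaf size {1, 5}; the grid is unstated in the
source protocol and deliberately small and config-driven. Tuning is
performed per cell (task × placement set). The final model is refit on the
whole development set and predictions are emitted for outer-test
participants only; the API offers no path by which test windows can reach
training, and the test suite asserts exclusivity over every cell. Class
imbalance is handled at the metric level only (no resampling or class
weights by default).

The random forest itself is implemented in compiled code inside the package
(bootstrap-resampled CART trees, Gini impurity for classification, variance
reduction for regression, per-node feature subsampling, majority-vote or
mean aggregation) because the target environment provides no forest
learner. It uses R's RNG, so every fit is reproducible from a seed; all
seeds derive from one master seed by hashing identifying strings, making
cells independent and the experiment resumable cell by cell.

### Reporting

Per task, combinations are ranked by their difference from the all-five
combination, grouped by sensor count, sorted within group (decreasing for
accuracy metrics, increasing for RMSE; ranking uses unrounded values,
display rounds to two decimals). The guideline rule selects the *most
efficient combination*: among combinations within a similarity margin of
the best one (default 10%, relative mode; for RMSE the margin is applied
upward), take the fewest sensors, breaking ties by the usability order
wrist > hip > ankle > upper arm > thigh applied to each candidate's most
usable member, then by lexicographic code.

Two margin interpretations are implemented — relative (within
`margin × best`) and absolute (within `margin` on the metric scale) —
because published selections of this kind are ambiguous between them: a
0.51-vs-0.57 accuracy pair fails a strict relative 10% rule (gap 10.5%) but
passes an absolute 0.10 rule. Neither mode is asserted as "the" intent.
One known irreproducibility is documented in the tests: for the MET task,
published guideline tables can pick a two-sensor hip+wrist combination even
when a single hip sensor also lies within the stated margin of the best
combination; under the fewest-sensors-first rule implemented here the
single hip wins, and the corresponding acceptance expectation is left
failing rather than bending the rule to the answer.

## The synthetic cohort: what it emulates, and what it does not

Each activity has a per-placement *signal template*: a unit gravity axis
(device orientation, posture-dependent, with a small deterministic
per-activity tilt), sinusoidal components `(frequency, amplitude, axis-mix)`,
white sensor noise, and a slow random-walk drift whose total SD over the
session equals the template's `drift_sd`. A session is
`gravity + Σ sinusoids (scaled by the participant's amplitude factor)
+ noise + drift`. The amplitude factor multiplies only the movement
components — gravity is always 1 g and sensor noise is a device property —
which keeps the noiseless static case exactly equal to the gravity axis.
Sinusoid mixing vectors keep a substantial gravity-axis component: a tone
orthogonal to gravity enters the vector magnitude only at second order, and
the features operate on VM.

Stated-world defaults (chosen once, not tuned):

* 32 activities: 4 sedentary (METs 1.0-1.45, near-static, noise ~0.01-0.02 g),
  6 locomotion (METs 2.8-4.55, cadence 0.8-2.05 Hz — inside the 0.6-2.5 Hz
  band — with a first harmonic; ankle > thigh > hip > wrist > arm
  amplitudes), 22 lifestyle (METs 1.8-4.2, slow 0.3-1.5 Hz rhythms plus a
  2.7-3.9 Hz arm component, wrist/arm noise 0.10-0.12 g dominating the
  other placements). Movement amplitudes scale with `MET − 1`, which is
  what makes MET regression learnable from amplitude features.
* Durations uniform in 360-480 s (6-8 min); 100 Hz; activities scheduled
  sequentially with 7-min rests.
* Participants: log-normal amplitude factor (σ = 0.10) and a Gaussian MET
  offset with a 0.25-MET between-participant SD (each activity's
  between-participant SD scales this shared draw, so a participant is
  consistently above or below average across tasks).
* VO2: exponential onset with τ = 40 s from rest (3.5) to
  `3.5 × (MET mean + offset)`; shifted-exponential breath intervals with a
  3-s mean (irregular by design, to force time-based smoothing); 1.0
  mL·min⁻¹·kg⁻¹ breath-level noise (0 for noiseless fixtures). With
  τ = 40 s and a 120-s onset cut, the closed-form onset deficit keeps the
  recovered MET within 0.03 of truth for METs up to ~5, comfortably inside
  the ±0.15 recovery contract.
* With the 32/4 roster and equal durations, sedentary windows are ~12.5% of
  epochs — a small minority, bracketing the single-digit share seen in
  comparable protocols.

A green test on this cohort establishes that the *pipeline* is correct —
features discriminate where the generator puts discriminative structure,
folds never leak, metrics and selection rules follow their definitions. It
does **not** establish field performance: sinusoid-plus-noise signals are
far cleaner than real human movement, there are no transitions, non-wear,
posture errors or device miscalibration, and between-participant movement
idiosyncrasy is a single scalar. Absolute synthetic accuracies are
therefore optimistic, and only their orderings and the machinery are
meaningful.

## Scaling choices in the test suite

The acceptance tests state their scale-downs explicitly: forests of 8-100
trees with single-point grids replace the 300-tree tuned default; the
superset-does-no-harm property runs on 3 seeds × 2 placements instead of
≥5 seeds × all 31 sets; and the label-permutation null uses the fixture's
8 activities (chance 1/8) rather than 32. Generator parameters, cohort
sizes and seeds are never adjusted to outcomes.

## Known limitations

* No biomechanical gait model, wear-side effects, or device physics; the
  generator is a statistical stand-in.
* Random forest only; rankings under other learners may differ and are out
  of scope.
* No activity-count conversion, autocalibration, or non-wear detection on
  the raw-signal side; no respiratory-exchange artifacts on the VO2 side.
* The session-mean MET is the regression target for every window of the
  session; time-aligned MET targets are not attempted.
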