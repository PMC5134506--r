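---
title: "Counting overhead arm motions from a wearable IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting overhead arm motions from a wearable IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`armspot` turns a 50 Hz log from a single upper-arm IMU (tri-axial
accelerometer in g, rate gyroscope in °/s, magnetometer unit-direction) into
per-session counts of baseball throws and volleyball serves, against a
background of rest and resisted shoulder exercises. This vignette documents
the model at each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic test bed does and does not
establish.

## Conventions

The device x-axis points along the arm; y and z complete a right-handed
device frame. The world frame is z-up with x toward the horizontal
projection of magnetic North; nadir is (0, 0, −1). A stationary device whose
x-axis points at nadir reads `ax = +1` g — i.e. the accelerometer triplet
measures the direction of the gravity vector in the device frame. This is
the convention that makes `θ = cos⁻¹(ax/‖a‖)` read 0° for a hanging arm and
180° overhead. The gyroscope is kept sensor-native in °/s and converted to
rad/s only inside integration. Recordings must be strictly uniform
(`|Δt − 1/fs| < 0.1/fs`); violations are rejected, never resampled, because
every downstream stage (debounce windows, FFT bins, fixed windows) assumes
the nominal rate.

## Orientation: two elevation estimators

The accelerometer-only estimator `θ = cos⁻¹(ax/‖a‖)` is exact while the
device is quasi-static, but a throw superimposes several g of linear
acceleration on gravity, and the estimate fails precisely during the events
of interest. The filtered estimator fuses all three sensors into a unit
quaternion `q` (device → world) and reads elevation off the direction
cosine matrix: `θ = cos⁻¹((DCM·[1 0 0]ᵀ)·[0 0 −1]ᵀ)`, with the dot product
clamped into [−1, 1] before the arccosine to guard rounding.

The filter itself is a propagate-then-correct design with a single gain:

* **Propagation** applies the exact quaternion exponential of the measured
  rate over one sample, `q ← q ⊗ exp(½ ω Δt)`. At mid-throw rates
  (~2000 °/s ≈ 40° per sample at 50 Hz) a first-order Euler step loses
  about 2° per sample; the closed form keeps gyro-only integration of a
  constant rate within 0.2° per 90° rotated, which the tests assert.
* **Correction** is a normalized gradient-descent step on the combined
  alignment objective `f(q) = R(q)ᵀ v_ref − v_meas` for the gravity
  reference (0, 0, 1) (the accelerometer direction, sign-flipped into the
  "up" convention) and the Earth-field reference `b = (‖h_xy‖, 0, h_z)`
  rebuilt from the current estimate, which makes the magnetometer constrain
  heading only — magnetic dip or distortion cannot corrupt elevation. The
  step magnitude is the configured `gain` in rad/s (default 0.1),
  independent of the error size. A constant-magnitude step rather than a
  proportional one is deliberate: it absorbs any gyro bias below
  `gain` rad/s (≈ 5.7 °/s, comfortably above the ≤ 2 °/s the noise model
  injects) with vanishing residual error, where a proportional correction
  at the same gain would settle ~20° away. The Jacobians of `R(q)ᵀ v` are
  implemented analytically and verified against numerical gradients in the
  test suite.
* **Initialization** is TRIAD-style from the first accelerometer +
  magnetometer sample (policy `"triad"`, the default), so static recordings
  start converged; `"identity"` exists to exercise convergence, which
  proceeds at the gain's rate (~6°/s of error reduction).

During a 2 s window around simulated ball-release impulses the fused
elevation stays within 3° RMS of ground truth while the accelerometer-only
estimate is off by ~11° RMS; on static data the two estimators agree within
1° after a 1 s warm-up. Gyro bias is otherwise not estimated online, and no
hard/soft-iron magnetometer calibration is attempted.

## Event-count histograms

`hist_and_count()` assigns every sample of a scalar series to its nearest
bin center (absolute distance, ties to the lower index so results are
platform-independent) and keeps two counts per bin: the classic sample
count, and a debounced event count. The event counter increments only when
the bin's previous occupancy lies more than `event_spread = 1 × fs` samples
in the past, and the last-occupancy marker refreshes on *every* sample
assigned to the bin, so a sustained reach counts once and a full second of
absence is required before the next count. Two initialization details
matter: markers start at `−event_spread − 1` so an event inside the first
second of data is counted, and the production path (vectorized per-bin gap
scan) is verified against a literal per-sample re-scan implementation on a
thousand random series in the acceptance suite. Default bins are 20°-wide
for elevation and 150 °/s-wide for rate magnitude up to 3000 °/s; both are
arguments, since any clinically interesting edge ("how often above 90°?")
is a bin-design question.

## Stage 1: gesture spotting

A sample is hot when elevation > 45° **and** rate magnitude > 400 °/s, both
strict, as the rule is printed. The conjunction is the null-class workhorse:
slow elevated motion (resisted flexion reaches ~165° at ~200 °/s) and fast
unelevated motion both fail it. Runs of hot samples with gaps below the
refractory period (1.0 s, matching the event-counter debounce) merge into
one detection anchored at the run's rate-magnitude peak — the anchor choice
is open in principle (first trigger vs. peak); the peak is used because the
simulator's ground truth marks peak-rate times and because it centres the
window on the most informative part of the gesture. The extracted window is
2.0 s long with 40% before the anchor (both configurable): at 50 Hz that is
100 samples, enough to hold wind-up and follow-through of either sport.
Edge-truncated windows are zero-padded to nominal length and flagged.

One caveat is worth stating: debounced event counts are not mathematically
monotone in the thresholds (raising a threshold can split a >1 s hot run
into two separated bursts). For physiological signals, whose hot runs are
sub-second, monotonicity holds, and the property tests assert it on
band-limited random series; adversarial step functions can violate it.

## Stage 2: features and classification

Each 100-sample segment yields exactly 81 named features:

* 36 summary statistics — min, max, range, median of acceleration, rotation
  rate, and per-axis elevation relative to gravity (the angle between each
  device axis and nadir, from the fused orientation), for all three axes;
* 3 — the rotation-rate vector at the sample of maximum arm elevation;
* 3 — the unit rotation-axis components at the sample of maximum
  rotation-rate magnitude (the zero vector when the peak rate is < 1 °/s,
  so degenerate segments stay finite);
* 39 — mean FFT magnitudes of the rotation rate in 13 bands per axis.

The spectra are magnitudes of the unwindowed FFT normalized by segment
length; a band [lo, hi) averages the bins whose center frequency falls in
it, with the Nyquist bin folded into bands ending at 25 Hz. Because
magnitudes are used, the features are exactly invariant under circular time
shifts, which the tests assert to 1e−9. The band set is multi-resolution:
six coarse bands 0–0.5, 0.5–1.5, 1.5–2.5, 2.5–5, 5–10 and 10–25 Hz
partition (0, 25] exactly once and include every band the reduced
classifier uses as a single feature; seven finer sub-bands (5–7.5, 7.5–10,
10–12.5, 12.5–15, 15–17.5, 17.5–20, 20–25 Hz) refine the two wide bands and
bring the registry to 81. A flat 13-band partition cannot contain both
5–10 Hz and 10–25 Hz as single bands, so nesting was chosen over either
splitting the named bands or inventing sliver bands.

The default classifier runs on eight features — rotation-axis x and z at
peak rate, x-axis range of motion relative to gravity, and the band means
y 5–10, y 10–25, z 0–0.5, z 2.5–5 and x 0.5–1.5 Hz. `forward_select()`
reproduces that kind of reduction generically: a greedy wrapper that adds
whichever feature maximizes stratified k-fold cross-validated accuracy of
the stage-2 ensemble, stopping at `k` features or at the first no-improvement
plateau. Selection uses smaller ensembles (50 trees, 5 folds) than the final
fit purely for cost; both are arguments, and everything is deterministic
given the seed.

The ensemble is bootstrap aggregation of 160 unpruned CART trees — realized
as a random forest with `mtry` equal to the number of features, which is
exactly bagging — fit on a stratified 40% training split; the remaining 60%
is recorded in the model object as the held-out evaluation set. A segment's
class scores are tree-vote fractions (they sum to one by construction; no
calibration is applied), and the null-class gate assigns the best sport
class only when its score is at least 0.60 — inclusive, since the rule is
"at least 60%". Training data from the simulator labels strict-rule
detections near true sport repetitions as Throw/Serve; the Neither class is
harvested with a loosened rule (rate > 150 °/s) whose extra detections are
exercise segments, mirroring how false detections would populate a null
class in deployment.

## Agreement statistics

`bland_altman()` fixes the sign convention as algorithm − observed, so
undercounting yields a negative mean difference. Both a t-based 95%
confidence interval of the mean difference (n − 1 df) and classical
1.96·sd limits of agreement are computed and labelled separately, because a
printed "95% confidence interval" around a mean difference does not
disambiguate the two. Degenerate inputs are flagged rather than silently
propagated: constant differences collapse both intervals to the mean, and
Pearson r is reported as undefined when either count vector is constant.

## The simulator and what it shows

Activity templates are minimum-jerk keyframe trajectories in three angle
channels — elevation α, rotation about the arm axis φ, heading ψ — composed
as `q(t) = Rz(ψ)·Ry(90° − α)·Rx(φ)`. Minimum-jerk segments are twice
differentiable with zero velocity and acceleration at every keyframe, so
the angular rate is continuous and the emitted gyro (a quaternion central
difference at 1 ms) matches a numerical derivative of the true trajectory
to < 1 °/s RMS, which the tests verify against a 4×-oversampled copy of the
truth. Throws are internal-rotation-dominant (fast about device x, nominal
peak ≈ 2100 °/s, up to ~2500 with intensity and subject scaling), serves
are elevation-plane-dominant and slower (≈ 1400 °/s) with longer swings,
so the two sports separate in both rotation-axis and spectral features;
exercises keep elevated-phase rates below ~350 °/s under the largest
intensity draws, so they cannot cross the 45°/400 °/s rule. Ball release
and contact add Gaussian-bell linear-acceleration impulses (3.5 g / 2.5 g,
50–70 ms) that corrupt the accelerometer exactly when a naive estimator is
most tempted to trust it.

Noise defaults — 1 °/s rms gyro noise with a constant per-axis bias drawn
within ±2 °/s, 0.02 g accelerometer noise, 0.005 magnetometer noise — are
plausible for the consumer MEMS class of sensor; per-axis gyro saturation
(±2000 °/s full-scale) is available but off by default so multi-axis
composition can reach the ~2400 °/s magnitudes a hard throw produces.
`default_benchmark_suite()` emulates a two-session protocol per subject:
a control session of eight repetitions per activity in a fixed order, and
a randomized session with shuffled order, 2–6 repetitions per exercise and
4–12 per sport, with a ±15% per-subject kinematic scale. All randomness
derives from one seed per script.

The suite sizes used by the tests and the acceptance script are a deliberate
compromise: the classifier is trained on an 11-subject control panel
(~480 labelled segments) and evaluated on 20 randomized sessions plus an
exercises-only negative control; the event-counter oracle sweep uses 1000
random series up to 10⁴ samples. On these conditions the pipeline recovers
per-session counts essentially exactly (recall ≥ 0.85 required, ≈ 1.0
observed; mean signed count error within ±1 required, ≈ 0 observed).

What this does and does not show: the simulator provides exact ground truth
and honest sensor corruption, but its classes are cleaner than human data —
real throwing kinematics vary within and between subjects far more than a
±15% amplitude scale, linear acceleration at the sensor includes centripetal
components the model omits, magnetometer disturbance indoors is structured
rather than white, and the null class in the field is open-ended rather
than seven scripted exercises. Passing the synthetic recovery study
therefore validates the pipeline's mechanics (fusion, spotting, windowing,
features, gating, counting), not field accuracy; human-subject results for
this architecture sit around 94% classification accuracy on
control data and ~84–94% per-class count accuracy under randomized
validation, and the bundled reference confusion matrices preserve that
arithmetic for comparison.

## Known limitations

* No gyro-bias state or magnetometer calibration in the filter; biases
  beyond the gain's absorption range (> ~5 °/s) would degrade tracking.
* The spotting rule is tuned for high-intensity overhead gestures; slower
  sport motions (lobs, underhand serves) would need a second detector bank,
  which the architecture anticipates but this package does not implement.
* Event counts from debounced histograms double-count a motion that lingers
  near a bin boundary for more than a second, and a reach to 170° also
  increments every lower elevation bin it passes through; both are inherent
  to the method, not bugs.
* Feature selection is a greedy wrapper; it is deterministic given a seed
  but not guaranteed to find the globally best subset.
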