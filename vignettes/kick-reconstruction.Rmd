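---
title: "How instep reconstructs a kick: model, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How instep reconstructs a kick: model, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instep)
```

`instep` turns a single foot-mounted six-axis IMU recording of a football
instep kick into a world-frame 3D trajectory and a small set of kick-quality
metrics. This vignette explains the model behind each stage, the thresholds
that matter and why they have the defaults they do, what the built-in
simulator does and does not emulate, and the numerical choices made where
more than one reasonable implementation exists.

## The measurement model

An accelerometer measures *specific force* — kinematic acceleration minus
gravity, in the sensor's own frame. A gyroscope measures the angular rate of
that frame. To recover position, the pipeline must (a) undo per-axis sensor
deviations, (b) track the sensor's orientation so accelerations can be
expressed in a fixed frame, (c) remove gravity, and (d) integrate twice
without letting small errors grow quadratically in time. Each stage below
corresponds to one exported function; `reconstruct_track()` chains them.

### Sphere-model accelerometer calibration

At rest the true specific force has norm exactly 1 g, whatever the
orientation, so static readings taken at many orientations lie on the unit
sphere. A real sensor follows `G = L(g + b)` with diagonal per-axis scale
`L` and bias `b`, turning the sphere into an offset axis-aligned ellipsoid.
`fit_accel_sphere()` estimates the model in two linear least-squares passes:

1. assuming unit scale, `|x − c|² = r²` is linearized (`2x·c + (r² − |c|²) =
   |x|²`) and solved for the centre `c = Lb`;
2. with the centre removed, `Σ (y_i / L_i)² = 1` is linear in `1/L_i²` and
   solved for the scales.

Both passes are exact when only one deviation is present (bias-only data
recovers `b` to machine precision; a centred ellipsoid recovers `L`
likewise); with both present the first pass's unit-scale assumption leaves a
residual of order `|b|·|L − I|`, about 1e-4 g at realistic deviations —
far below what the downstream gates can notice. `L` is restricted to a
diagonal: the deviation being modelled is per-axis proportional error, and
static data at 1 g cannot reliably separate cross-axis terms from tilt.

Even a fitted model leaves the static norm slightly off unity, so
`apply_calibration()` ends with a *normalization*: the whole stream is
rescaled by the mean norm of its static window so that the window's mean
norm is exactly 1 g. The rescale is per-stream rather than a one-time sensor
constant — it then also absorbs slow gain drift between sessions, and costs
nothing when the sensor is stable.

As an extension that is on by default (`fix_gyro_bias = TRUE`), the
gyroscope bias is estimated as the mean rate over the same static window and
subtracted. Gyro bias is the single largest driver of attitude drift in a
pure-integration pipeline; with a 500-sample static lead available there is
no reason not to remove it. It can be switched off to study its effect.

### Attitude from angular rate

Orientation is tracked as a unit quaternion (Hamilton convention, scalar
first) relative to the *initial* frame — the sensor frame during the static
lead. Each step applies the quaternion kinematic equation

`q_k = normalize( q_{k−1} + ½ · q_{k−1} ⊗ (0, ω) · Δt )`

and renormalizes immediately, so unit norm is preserved to 1e−12 at every
sample. For a constant axis this scheme's angle error per step is
`(ωΔt)³/12`, i.e. second-order overall: at 100 Hz a 90° rotation lands
within 0.002°, and halving Δt quarters the error (both are asserted in the
test suite).

One stream-level choice: the rate driving the step from sample *k−1* to *k*
is the average `(ω_{k−1} + ω_k)/2` — the same averaged-sample idea the
integrator uses for velocity. Feeding the raw right-endpoint rate instead
leaves a first-order error term proportional to `Δt · dω/dt` while the rate
is changing, which on a kick (rates swinging by rad/s within tenths of a
second) costs roughly a centimetre of end-point position; the averaged form
removes it at no cost. `update_attitude()` itself remains the one-step
contract above.

There is no magnetometer and no accelerometer aiding: attitude is pure gyro
integration. Over the ~2 s of a kick that is accurate to a small fraction of
a degree; it would not be over minutes.

### Gravity compensation and tilt leveling

Gravity is constant in the initial frame, so subtracting the mean rotated
acceleration over the static window (`static_offset()`, default 500
samples) removes it exactly — to the extent the attitude is right — along
with any residual accelerometer offset. The offset's norm is checked against
1 g (±5%) to catch captures that were not actually static.

The initial frame is generally tilted. The static offset reveals the tilt,
and the frame is leveled with two rotations (yaw stays 0 — it is
unobservable and only fixes the arbitrary compass heading of the result):

* `roll = atan2(offset_y, offset_z)`
* `pitch = −atan( offset_x / √(offset_y² + offset_z²) )`
* `T = Rz(0) · Ry(pitch) · Rx(roll)`

The pitch formula uses the full `√(offset_y² + offset_z²)` denominator
rather than `offset_z` alone. The two agree exactly when roll is zero and to
first order always, but only the former levels the offset *exactly* under
combined roll and pitch (the package asserts `|T·offset|_{x,y} < 1e−9 g`
for tilts to 15°); the `offset_z`-only variant leaves an O(tilt²) horizontal
gravity residual that double integration would happily turn into
centimetres. A sensor lying on its side (`offset_z` near 0) makes the
decomposition degenerate and is rejected.

### Gating, integration and zero-velocity updates

Three thresholds, all in `imu_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `accel_gate` | 0.392 (= 0.04 g) | m/s² | zero any sample whose *vector norm* is below the gate |
| `zupt_run_length` | 15 | samples | consecutive gated-zero samples that declare "stationary" |
| `vel_gate` | 0.196 | m/s | clamp residual velocity inside a detected static run |
| `static_window` | 500 | samples | gravity/bias estimation window |

The gate is applied to the norm, not per axis: per-axis gating would bend
the direction of small accelerations. It runs *after* gravity removal, so
"zero" means "below the sensor's noise floor plus compensation residual";
an instep kick's accelerations sit far above 0.392 m/s² except at the very
ends of each swing phase, so the gate removes drift fuel without biting the
motion. Gating also manufactures the exact-zero runs the stationarity test
needs — on real (noisy, but ungated) data, fifteen *exactly* zero samples
would never occur.

Integration uses the averaged-sample rule `v_i = v_{i−1} + (a_i +
a_{i−1})/2 · Δt` per axis — the trapezoid rule, exact for piecewise-linear
acceleration — and the same rule again for position. The track starts at
rest at the origin (`v₁ = 0`, `p₁ = 0`), which doubles as the first-step
convention; samples are assumed uniformly spaced at the configured rate.

When `zupt_run_length` consecutive gated accelerations are all exactly zero
the sensor is declared stationary and the velocity reset to zero — the
classic ZUPT that removes the "phantom constant velocity" left when
acceleration and deceleration areas do not cancel. The reset acts from
detection onward, not retroactively over the run: causal, simpler, and the
≤14 pre-detection samples carry at most a few millimetres of position. Once
stationary, velocity stays exactly zero until an above-gate sample arrives.
The secondary `vel_gate` clamp is scoped to detected static runs; a global
clamp would flatten the genuine slow start of the backswing.

## The simulator

`kick_truth()` builds the ground truth as three quintic segments in time
(backswing, downswing, follow-through) between knots with prescribed
position, velocity and acceleration, embedded in a static lead and tail.
The construction makes the commanded quantities *exact* rather than
approximate targets:

* the backswing apex knot has zero velocity and acceleration at height
  `backswing_height`, and the neighbouring segments approach it
  monotonically in z, so the pre-peak maximum height equals the commanded
  apex;
* the low-point knot carries velocity `(0, peak_speed, 0)` with zero
  acceleration — a critical point of speed — and the generator verifies
  numerically that no interior sample exceeds it, so the maximum sampled
  speed equals the commanded peak;
* the follow-through distance is the one free geometric parameter, solved
  with `uniroot()` so the sampled path length lands on
  `path_length_target` (path length is not monotone in that distance for
  very short follow-throughs, so the search starts from the minimizing
  value).

Knot times are snapped to the sample grid so these statements hold at
sample resolution, not just in the continuum. Orientation pitches about the
lateral axis through `orientation_sweep` (default 0.7 rad) on a
minimum-jerk time course, giving smooth, rest-to-rest angular rates.
Defaults — apex 0.756 m, peak 7.47 m/s, path 3.63 m, 1.4 s of motion,
600-sample lead — describe a representative adult instep kick at 100 Hz.

`simulate_imu()` inverts the truth through the full sensor model: a
mounting tilt drawn uniformly within ±10° (composed yaw-free, so the
pipeline's two-angle leveling is not asked to recover an unobservable
heading), rotation of gravity plus kinematic acceleration into the sensor
frame, the `G = L(g + b)` deviation model (default biases 0.025–0.04 g,
scales within 2% of unity), white Gaussian noise (0.05 m/s², 0.2 °/s), and
16-bit quantization at ±30 g / ±4000 °/s. All randomness flows from one
seed; equal seeds give bit-identical streams.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real recordings: ball impact (the modelled kick is an
empty swing, so no contact transient), soft-tissue and strap vibration,
gyro bias instability and temperature drift over the recording, axis
misalignment/cross-coupling, timestamp jitter, and any camera-side
digitization error in the reference. The simulator's reference is the
analytic truth itself, so agreement numbers speak to algorithmic error, not
to hardware-versus-camera agreement.

## Metrics and agreement

`kick_metrics()` reports the path length (chord sum), the maximum foot
speed with its sample and position (ties broken to the earliest sample),
and the backswing apex — the maximum height *before* the peak-speed sample,
relative to the starting height. A track whose speed peaks at its first
sample has no backswing phase and raises a phase error.

`compare_to_reference()` crops to the motion span (first sustained
above-gate sample to the last moving one), linearly interpolates the track
at the reference timestamps, and reports: 3D position RMSE; 3D velocity
RMSE; velocity RMSE along the kick direction (first principal component of
the reference positions, sign-aligned with the net displacement) — the
directional figure is the headline velocity number, matching how swing
accuracy is conventionally quoted; and per-axis Bland–Altman statistics
(bias, ±1.96 SD limits, fraction outside, plus a pooled count). Zero
variance collapses the limits to the bias and is reported, not raised.

## Validation sizes and results

The test suite and `scripts/acceptance.R` run entirely on simulated data at
the study scale: kicks of 841 samples (6 s lead + 1.4 s motion + 1 s tail
at 100 Hz), calibration sets of 24 orientations × 25 samples, ten seeds for
the end-to-end recovery study. These sizes keep the whole suite in tens of
seconds while leaving Monte-Carlo margins comfortably away from the
asserted bounds. Under those conditions the pipeline reconstructs the
default kick with mean 3D position RMSE below 0.01 m over a 3.63 m path,
kick-direction velocity RMSE below 0.01 m/s, and sub-percent errors on peak
speed and apex height — the acceptance script recomputes these figures on
demand.

## Known limitations

* Pure gyro attitude: fine for seconds, not minutes; no magnetometer or
  Kalman/complementary aiding (out of scope by design).
* Yaw is arbitrary: trajectories are reconstructed up to a rotation about
  the vertical; comparisons against an external reference assume the
  reference shares the heading (the simulator guarantees this).
* The recording must begin with a genuinely static lead at least as long as
  `static_window`; the pipeline checks the offset norm but cannot repair a
  moving "static" window.
* Uniform sampling is assumed; there is no timestamp-gap interpolation.
* File ingestion supports either raw unsigned 16-bit words or pre-scaled
  physical values (auto-detected), but not vendor binary formats or
  streaming input.
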