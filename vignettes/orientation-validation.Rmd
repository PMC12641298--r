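---
title: "Validating wearable MARG orientation estimates against optical motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable MARG orientation estimates against optical motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(margsense)
```

## The problem

Consumer-grade wearables increasingly carry a full 9-axis MARG unit — a
tri-axial accelerometer, gyroscope and magnetometer — which in principle lets
them track the 3-D orientation of the body segment they are strapped to, and
hence support movement-*quality* assessment outside the laboratory. Whether
such estimates are trustworthy is an empirical question: the gold standard is
concurrent validity against an optical motion capture (OMC) system recording
the same movement, scored as the root-mean-square error (RMSE) between the
two orientation time series.

Getting from raw component logs to that comparison involves a surprising
amount of machinery, every stage of which can silently corrupt the result:

1. **Handedness** — the device logs in a left-handed sensor frame; all
   rotation math here is right-handed. `to_right_handed()` negates one
   documented axis (y), shared as a single constant with the simulator.
2. **Calibration** — `fit_magnetometer_ellipsoid()` removes hard-iron
   (additive) and soft-iron (linear) magnetic distortion;
   `estimate_gyro_bias()` removes the constant gyroscope bias using a static
   window.
3. **Temporal merging** — the three components start asynchronously and run
   at different rates (52/52/100 Hz); `merge_components()` crops to a common
   origin and interpolates onto one 52 Hz grid.
4. **Sensor fusion** — `run_filter()` advances a unit quaternion with the
   Madgwick gradient-descent filter (gain `beta = 0.1`).
5. **Cross-system alignment** — `resample()` to the 250 Hz reference rate,
   `synchronize()` (cross-correlation lag), `estimate_heading_offset()` /
   `apply_heading_correction()` (constant yaw offset between the sensor's
   geomagnetic frame and the laboratory frame), and `baseline_to_zero()`.
6. **Scoring** — `rmse_per_angle()`, z-score outlier exclusion across
   recordings, and the excellent/good/unacceptable categorisation at the
   5°/10° boundaries.

No real recordings ship with the package. Instead the synthetic-data module
forward-models *both* systems from a known ground-truth trajectory, so every
stage — and the pipeline end-to-end — is verifiable by parameter recovery:
simulate with known lag, heading offset, biases and iron distortion, run the
pipeline, and check that each quantity is recovered.

## The model

### Orientation state and conventions

Orientation is a unit quaternion $q$ (scalar-first), mapping sensor
coordinates to lab coordinates: $v_{lab} = q\,(0,v_{sensor})\,q^*$. For
reporting, $q$ is converted to Euler XYZ angles with the axis-to-name mapping
used for this device class: **X = pitch $\theta$, Y = roll $\phi$,
Z = yaw $\psi$**, composed extrinsically about the fixed lab axes:

$$R = R_z(\psi)\, R_y(\phi)\, R_x(\theta).$$

Two consequences are load-bearing. First, roll is the *middle* angle, so the
gimbal-lock singularity sits at $|\phi| = 90°$: as roll approaches 90°,
pitch and yaw lose a degree of freedom and their estimates blow up while
roll itself stays well-behaved — the package reproduces exactly this error
signature on the chair-dip-like profile. Second, yaw is rotation about the
*lab* vertical, so left-multiplying every sample's DCM by $R_z(\Delta\psi)$
shifts yaw alone and provably leaves static pitch/roll untouched. That
property is what makes the static heading correction well-defined; an
intrinsic X-then-Y-then-Z reading (i.e. $R_x R_y R_z$) does not have it,
which is why the extrinsic form was chosen. At the singularity the
conversion assigns the free angle to yaw, sets pitch to 0 and raises a
`gimbal` flag rather than throwing.

### The fusion filter

`madgwick_update()` implements the standard MARG form: the quaternion rate
from the gyroscope, $\dot q = \tfrac12 q \otimes (0,\omega)$, is corrected by
$-\beta$ times the *normalized* gradient of the combined
gravity-plus-field objective; the magnetic reference is re-decomposed into
horizontal and vertical components $(b_x, 0, b_z)$ at every step so the
magnetometer can only correct heading, never tilt. Two numerical details
matter in practice:

* **Trapezoidal gyro integration.** Each step uses the mean of the bracketing
  gyro samples. Left-endpoint integration carries a systematic delay of half
  a sample (~10 ms at 52 Hz), which shows up verbatim as a synchronization
  lag bias.
* **The $\beta\,dt$ limit cycle.** Because the corrective step is
  *normalized*, its magnitude is always $\beta\,dt$ (~0.11° at the
  defaults), independent of the error size. Converged estimates therefore
  jitter inside a ~0.1–0.2° limit cycle, and convergence speed from a wrong
  initial orientation is capped at $\beta$ rad/s (~5.7°/s at
  $\beta = 0.1$): an arbitrary initial error needs tens of seconds of static
  data, a 20° error closes within 5 s. Both behaviours are inherent to the
  published algorithm, not implementation artefacts.

The initial quaternion defaults to `"from-first-sample"`: a TRIAD-style
analytic orientation from the first accelerometer/magnetometer pair
(`orientation_from_accel_mag()`), exact for the static pose that starts
every set.

### Magnetometer calibration

Iron distortion maps the sphere a rotating magnetometer should trace into an
offset ellipsoid: $m = S\,R^\top f + h$. The fit solves the 9-parameter
linear least-squares quadric $x^\top M x + 2k^\top x = 1$, factors it into
centre $c = -M^{-1}k$ (hard iron) and inverse shape
$A = (M/s)^{1/2},\; s = 1 + c^\top M c$ (soft-iron inverse), and normalizes
$\det A = 1$ with the implied radius reported as `field_magnitude` — the
filter uses only the field *direction*, so the normalization is a free
choice. On noise-free forward-modelled distortion the inversion is exact to
machine precision; with 1% radial noise and 500 points the hard iron is
recovered well within 1% of the radius.

One honest subtlety: a *single exercise set* cannot calibrate a
magnetometer. One set's orientations trace a one-dimensional arc, so the
magnetometer cloud lies on a curve that infinitely many quadrics fit; the
ellipsoid fit correctly raises a degenerate-geometry error rather than
returning a silent identity. The package therefore models what practitioners
actually do: `simulate_calibration_recording()` produces a sphere-covering
tumble maneuver, the session-level fit from it is passed into
`process_recording(mag_cal = )`, and a flag-controlled per-recording fit
remains available for data that does span enough directions.

### Gyroscope bias

Over a static window the true angular rate is zero, so the per-axis mean
reading is the bias. The window must pass a static gate (detrended RMS below
`gate_dps`, default 3 deg/s, with the offending axis named on failure);
with `window = NULL` the quietest 3-s span is auto-detected, which is robust
to the unknown clock offset before synchronization. With 5 s of 52 Hz data
the estimate is within $3\sigma/\sqrt{260}$ per axis.

### Alignment

* **Synchronization.** The two systems are triggered independently; the lag
  is the argmax of the normalized cross-correlation of one Euler channel,
  refined to sub-sample precision by parabolic interpolation of the peak.
  Correlation is computed on the circular (cos/sin) embedding of the angle
  and the channel is chosen by circular variance. The embedding matters:
  unwrapped angles turn the 180° pitch/yaw flips of gimbal-crossing
  trajectories into a drifting staircase that destroys the correlation peak,
  while the circular form treats the flips as genuine shared features and is
  identical to ordinary correlation for smooth signals. Constructed shifts
  are recovered to < 0.1 sample across the ±2 s search range; a manual-lag
  override exists.
* **Heading.** $\Delta\psi$ is the *circular* mean of (reference yaw −
  sensor yaw) over a static window (the interior of the 5-s lead pose by
  default), so offsets straddling ±180° average correctly (−179° vs +179°
  gives −2°, not +358°). Circular means are used for all angle averaging.
* **Baselining.** Both series subtract their per-angle circular mean over
  the *same* static window, making absolute orientations comparable despite
  the approximate manual sensor-to-segment alignment.

The fixed stage order is: handedness → calibration → crop → merge to 52 Hz →
fuse → resample to 250 Hz → synchronize → heading-correct → baseline →
score.

### Scoring

`rmse_per_angle()` wraps every per-sample difference to (−180°, 180°] before
squaring, and reports the fraction of reference samples with |roll| above
the 85° gimbal gate. Across recordings, `exclude_outliers()` makes a single
non-iterative pass with |z| > 1.96 on the raw values (zero spread keeps
everything; fewer than 3 values is an error since spread cannot be judged).
Categories: mean RMSE below 5° is *excellent*, 5–10° inclusive *good*,
above 10° *unacceptable*; both boundary values map to "good" and the
boundaries are configuration-visible. `summarize_validation()` applies the
exclusion per placement × movement × angle cell and reports kept-set and
raw-set SDs; empty cells render as missing, mirroring conditions a study
excludes (e.g. marker occlusion).

## The synthetic cohort: what it emulates, and what it does not

`movement_profile()` describes one exercise set the way the validation
protocol prescribes it: a 5-s static lead, 10 raised-cosine repetition
cycles (~3 s each), and a 5-s static tail; three sets per movement. The
raised-cosine shape was chosen over a sinusoid so repetitions dwell at
end-range, as real exercise does. Presets sketch the four analysed
exercises — squat, push-up, good-morning (pitch-dominant, 30–70°
amplitudes), and chair-dip, whose 100° roll excursion deliberately drives
the trajectory through the gimbal singularity. `simulate_marg()`
forward-models the datasheet device (±8 g / 52 Hz accelerometer,
±2000 deg/s / 52 Hz gyroscope, 100 Hz magnetometer, left-handed logging,
asynchronous component starts), and `simulate_omc()` the 250 Hz reference in
a lab frame rotated by a constant yaw offset. Default error terms are the
study conditions used throughout the recovery checks: gyro bias 1 deg/s per
axis, accelerometer noise 0.02 g, hard iron (0.3, 0, 0) gauss, soft iron
diag(1.2, 1.0, 0.8), component start offsets (0, 0.12, 0.31) s, and an
0.8 s inter-system clock offset. Lab conventions: gravity (0, 0, −1) g and
a 0.5 gauss field dipping 60° below horizontal with lab +x as magnetic
north — a mid-latitude default, fully parameterized.

What passing recovery tests on this cohort *shows* is that the pipeline's
algebra, frame bookkeeping, timing and scoring are correct, and that its
failure modes (uncalibrated iron degrading yaw; gimbal lock inflating pitch
and yaw with roll untouched) have the right direction and rough magnitude.
What it does *not* show is field accuracy on real limbs: the generator has
no soft-tissue artefact or skin motion, zero linear acceleration by default
(a hook exists), band-limited Gaussian noise in place of the device's
proprietary onboard filtering, a static uniform magnetic field with no
environmental interference, and an orientation-level reference with no
marker-model error. Real RMSEs will be larger, sometimes much larger, for
exactly the reasons the original validation found.

## Numerical choices and degenerate inputs

* Problem sizes: one set at 250 Hz truth rate is ~10k reference samples and
  ~2k fusion steps; a full scripted run (recovery, ablation, calibration
  Monte-Carlo, alignment sweeps, gimbal profile) completes in well under a
  minute on one core. These sizes were chosen as the smallest that leave the
  Monte-Carlo error far below every tolerance being checked.
* Quaternion interpolation is normalized-linear (nlerp) with hemisphere
  alignment — indistinguishable from slerp at the dense rates used; truth
  angular velocity is obtained by central differences of the quaternion
  series, $\omega = 2\,\mathrm{vec}(q^* \dot q)$.
* `resample()` interpolates angle streams on the unwrapped representation
  and rewraps, so seam-crossing ramps do not spike; it truncates rather
  than extrapolates.
* Degenerate inputs fail loudly: coplanar magnetometer clouds, non-static
  bias windows (with the offending axis RMS), disjoint component spans,
  flat series offered for synchronization, double handedness conversion,
  fewer than 3 values for outlier exclusion, negative RMSEs.
* Determinism: every stochastic step takes an explicit integer seed;
  identical seeds give bit-identical recordings, output trees and reports.

## Known limitations

* The flipped-axis constant (y) is an assumption shared by simulator and
  pipeline; ingesting real device logs would require verifying it against
  hardware.
* The heading correction is estimated once from the lead static pose
  (pooling with the tail pose is available); slow magnetic-heading wander
  under accelerometer noise means a single set's yaw RMSE has a heavy right
  tail — averaging over a protocol's sets is the intended use.
* No magnetic-disturbance rejection gate, matching the validated pipeline; a
  hook exists for future work.
* Euler-angle RMSE near the gimbal singularity measures representation
  instability as much as sensor error; the `gimbal_fraction` flag marks
  affected cells but the package deliberately does not switch to a
  quaternion error metric, because the decoupled per-angle report is the
  point of comparison.

## A worked run

```{r worked, eval = FALSE}
library(margsense)

profile <- movement_profile("squat")
truth <- make_trajectory(profile, rate = 250)

noise <- noise_spec(seed = 11)                    # study-condition defaults
recording <- simulate_marg(truth, noise = noise, clock_offset = 0.8)
reference <- simulate_omc(truth, frame_yaw_offset = 37)

mag_cal <- fit_magnetometer_ellipsoid(
  to_right_handed(simulate_calibration_recording(noise = noise)))

fit <- process_recording(recording, reference, mag_cal = mag_cal)
fit          # lag ~0.8 s, heading ~37 deg, sub-degree RMSE
tidy(fit)
autoplot(fit)
```
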