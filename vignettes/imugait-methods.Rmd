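---
title: "Methods: IMU gait kinematics, drift correction and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU gait kinematics, drift correction and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

This vignette documents the models behind `imugait`, the assumptions they
rest on, the numerical choices made where the design was open, and what the
package's synthetic benchmark does and does not demonstrate about real
recordings.

## The measurement model

A wearable network of up to seven MEMS IMUs (trunk; left/right thigh, shank,
foot) reports tri-axial gyroscope and accelerometer samples as signed 16-bit
counts. With a ±2000 °/s gyroscope and a ±8 g accelerometer the fixed
count-to-physical factors are 0.06 °/s per count and 0.00024 g per count.
Only sagittal-plane kinematics are estimated: the mediolateral gyro axis (y)
carries the segment's angular rate, and the anterior (x) and longitudinal
(z) accelerometer axes carry the gravity projection. Out-of-plane axes carry
bias and noise only. This mirrors the fact that flexion–extension is the
clinically dominant motion in gait and keeps every estimator scalar.

## Static calibration

Each trial opens with a 10-s quiet-standing window (N-pose). Per sensor:

* **Gyro offset** — the mean of the *scaled* samples per axis
  (counts × 0.06), subtracted from every subsequent scaled sample. Computing
  the offset on scaled values rather than raw counts keeps the subtraction
  unit-consistent; with a fixed scale factor the two readings differ only in
  where the multiplication happens.
* **Accelerometer norm** — `‖ACC‖ = sqrt(mean(ax)² + mean(ay)² + mean(az)²)`
  in counts. Calibration divides raw counts by this norm, which is a min–max
  normalization with bounds ±‖ACC‖: a static sensor then reads a unit
  gravity vector. The 0.00024 factor cancels in this ratio and is retained
  only for reporting raw axes in g.

State is initialized at zero and *replaced* at each calibration; nothing
carries over between trials, and periodic re-calibration replaces rather
than blends. Because the procedure assumes the wearer truly stands still,
windows whose scaled gyro standard deviation exceeds 3 °/s or whose
per-sample accelerometer norm varies by more than 5% are rejected: a
corrupted static pose would silently bias every downstream angle.

## Segment orientation

Fusion is initialized with the trigonometric accelerometer method,
`theta0 = atan2(a_x, a_z)·180/π`, averaged over the static window; samples
with norm below 0.5 g are refused since the gravity direction is then
unreliable.

**Complementary filter.** `θ_k = 0.98·(θ_{k−1} + ω_k/f_s) + 0.02·θ_acc,k`.
The 0.98/0.02 split trusts the gyro for short-term shape and the
accelerometer for the long-term mean; with zero inputs the recurrence decays
exactly as `θ_0·0.98^k`, which the tests pin down to machine precision.

**Kalman filter.** The published tuning is a pair of 2×2 matrices,
`Q = diag(0.005, 0.0003)` and `R = diag(0.0669, 0.039)`, without the state
or measurement vectors. The only two-dimensional pairing consistent with
those shapes uses state (angle, gyro bias) and the measured pair
(accelerometer angle, raw rate). Within that pairing we implement the
classic two-state attitude filter: the raw rate drives the prediction,
`θ ← θ + (ω − bias)/f_s`, with its variance `R[2,2]` propagated through the
integrator into the state covariance, and the accelerometer angle is the
update measurement with variance `R[1,1]`. The bias is observable through
the accumulated angle innovation; on a static stream a constant rate bias is
recovered to within 5% in under 10 s. The known weakness of this structure —
sustained one-directional rotation is briefly absorbed into the bias
estimate — is immaterial for periodic gait, whose rate averages to the bias
over each stride.

An alternative reading (the raw rate as a *direct* observation of the bias
state, `H = I`) was implemented first and rejected: the fast bias channel
chases the stride-frequency rate and the filter loses ~2° RMSE even on
noiseless signals.

**Pure integration** (`θ_k = θ_{k−1} + ω_k/f_s`, rectangular, with a
trapezoidal option) is kept as the drifting baseline: with a rate bias `b`
it drifts at exactly slope `b`, anchoring the drift metrics. Rectangular
integration matches a fixed-interval real-time loop; at 100–200 Hz the
scheme difference is far below the sensor noise floor.

## Joint angles

With neutral stance fixed at trunk 90°, thigh −90°, shank −90°, foot 0° (the
unique convention under which standing yields zero joint angles):

```
θ_ankle = −90 − θ_shank + θ_foot
θ_knee  = θ_thigh − θ_shank
θ_hip   = −(θ_trunk − θ_thigh − 180)
```

Leg segments are wrapped into [−270, 180]°, trunk and joints into
[−180, 180]°. Wrapping happens *after* the affine joint relations, never
inside them: the relations commute with consistent 360° shifts, and wrapping
first would clip continuous filter output mid-computation. The inverse map
(`joints_to_segments`) is exact, and the round trip is the identity to below
1e−9°, which the acceptance suite checks on 1000 random series. Joint
angular velocity uses central differences (second-order interior, one-sided
ends); the differentiator is a free choice and central differences dominate
one-sided ones at no cost. Left/right share one sign convention; mirroring
is left to the caller.

## Drift correction

Fusion outputs carry slow drift and constant offsets. The correction layer
learns a map from (estimated angle, angular velocity) to a reference angle.
All variables are min–max normalized to [−1, 1]; the inverse transform
restores degrees exactly.

* **Shallow NN** — one sigmoid hidden layer (5–20 neurons), linear output,
  least squares by Levenberg–Marquardt with an analytic Jacobian. Training
  stops when any of four rules fires: validation MSE rising for 10
  consecutive accepted iterations (15% of the training rows held out,
  seeded — the split fraction is our choice), MSE reaching 0, gradient below
  1e−7, or damping µ above 1e10; an epoch budget (300) backstops them. The
  weights returned are those at the best validation error. The trainer is
  authored in the package because no installed alternative provides LM
  backprop with validation early stopping; the stopping semantics, not the
  optimizer brand, are what make fits reproducible.
* **Regression trees** — `rpart` (anova method: binary splits maximizing MSE
  reduction), with leaf minima from {4, 12, 36, 50, 100} (fine to coarse)
  and a 200-observation branch minimum. `rpart`'s deterministic
  first-best-split tie-break stands in for the unspecified tie rule.
* **SVR** — `e1071` ε-insensitive regression; linear, quadratic, cubic
  (polynomial with `coef0 = 1`) or Gaussian kernel with
  `gamma = 1/(2σ²)`, σ ∈ {0.35, 1.35, 2.35}.

Cross-validation is 5-fold; when subject labels exist folds are contiguous
by subject, so every test subject is unseen — the user-independence the
correction layer claims. Fold NRMSE uses the same range normalization as the
metrics module. Whether the original evaluation was subject- or sample-wise
is unknowable from the text; subject-wise is the stricter reading and the
one we adopt.

## Agreement metrics

* **NRMSE** = RMSE / (max(ref) − min(ref)). The normalizing denominator is
  an open convention; range normalization makes NRMSE values of ~0.07–0.12
  plausible for joint angles with tens-of-degrees range of motion, where
  mean normalization would not, and it is invariant under a common shift of
  both signals.
* **XApEn(m, r)** = Φ_m − Φ_{m+1}, with Φ_m the mean log fraction of
  length-m templates of the test series matching templates of the reference
  under Chebyshev distance ≤ r, both series standardized first. Defaults
  m = 2, r = 0.2 (in SD units) follow the classical parameterization; both
  are exposed. Cross-matching can leave a template with zero matches;
  unmatched templates are excluded from the average at their level. A
  consequence worth knowing: in the small-r regime where exclusion is
  active, XApEn is *not* monotone in r; it is non-increasing in r once every
  template matches, and the property tests scope themselves to that regime.
* **Drift slope** — OLS slope of angle against time, reading drift as a
  linear trend. A pure sinusoid contributes O(12A/(ωT²)) to this slope even
  over whole periods, so on short windows the stride component can mask a
  small drift; drift measurements in the benchmark therefore use
  quiet-standing trials (zero-amplitude profiles) where the angle signal is
  drift plus noise only. An optional end-trim (default choice: first/last
  2 s when no stride annotations exist) excludes
  acceleration/deceleration transients.
* **Drift ratio** = |slope(test)|/|slope(ref)|; **turn increment** =
  100·(|slope after| − |slope before|)/|slope before|, around a marked 180°
  turn.
* **Bland–Altman** — mean difference and ±1.96 SD limits of agreement;
  **one-sample t-test** via `t.test`; **SUS** — odd items score
  response − 1, even items 5 − response, summed and ×2.5 per user, averaged
  over users.

Every metric is verified in the tests against an independently coded
brute-force oracle (explicit loops over the bare formulas), exact to 1e−10.

## The synthetic benchmark

`gait_profile()` builds per-joint harmonic series; flat-walking defaults
give hip −10..30°, knee 0..45° with its stance minimum at exactly 0°, ankle
±15°, cadences 90/105/120 steps/min for slow/normal/fast with ±10%
amplitude scaling, and terrain presets shifting offsets/amplitudes the way
ramps and stairs shift sagittal range of motion. These are one-time choices
of typical healthy-adult values. The left side lags the right by half a
stride. `synthesize_imu()` prepends a 10-s static prelude, converts the
backward-difference rate plus bias, white noise and drift offset to gyro
counts, projects unit gravity (plus noise) to accelerometer counts, and
quantizes by rounding half away from zero with ±32767 saturation —
emulating a 16-bit ADC without biasing the mean. Injected drift is a
constant rate offset switched on after the prelude, so the integrated angle
drifts at exactly the configured °/s; `inject_turn()` multiplies that
offset from the turn sample on, through an error-diffusion quantizer that
keeps the cumulative drift exact to one count.

What the simulator deliberately omits: segment linear acceleration (the
accelerometer sees gravity only, keeping the inclination oracle exact; a
real walker's foot sensor violates this during swing), soft-tissue artifact,
3D/out-of-plane motion, magnetometer effects, and foot-contact events.
Passing the synthetic benchmark therefore demonstrates the *algorithms* —
calibration algebra, filter recurrences, joint trigonometry, regression
machinery, metric formulas — not field accuracy on human recordings, which
depends on exactly the omitted effects. Problem sizes in the tests and the
acceptance script (30-s trials at 100 Hz, 1000-series round trips,
3000-sample regression fits) were chosen as the smallest sizes at which the
asymptotic behaviors (CLT bounds, drift slopes, CV stability) are clearly
expressed.

## Degenerate inputs and numerical conventions

Constant variables are refused by the min–max normalizer (undefined map);
constant references are refused by NRMSE and Pearson ρ (zero denominator);
zero accelerometer norm signals a sensor fault; free-fall samples are
refused by the inclination initializer; zero-variance samples are refused by
the t-test. A zero-variance series handed to XApEn is centered but not
scaled, so the identical-constants case returns exactly 0. The Kalman
covariance is symmetrized every step to hold positive semi-definiteness
against round-off. Timestamps are seconds as floats, sample indexing is
1-based in R, and every random draw in the package flows from an explicit
integer seed: the same seed gives bit-identical trials, fits and pipeline
output files.
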