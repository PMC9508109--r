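---
title: "Step-negotiation kinematics: models, generator design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-negotiation kinematics: models, generator design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quailkin)
```

# The analysis problem

Biplanar fluoroscopy of a walking bird yields two synchronized image streams
(laterolateral and ventrodorsal) sampled at 500 Hz. Turning them into joint
kinematics takes four stages, each implemented as a module of this package:

1. locate 22 skeletal landmarks in both views of every frame, from a handful
   of manually annotated frames (`train_landmark_regressors`,
   `predict_landmarks`);
2. calibrate each view's projection and triangulate the corresponded 2D
   observations to metric 3D (`calibrate_dlt`, `triangulate`);
3. express the motion in anatomical coordinates: pelvis and whole-leg frames,
   Cardan z–x–y angles, joint included angles, and the effective-leg
   variables of spring-mass gait models (`compute_kinematics`);
4. segment strides, normalize them to 100 samples, and compare conditions
   statistically (`segment_strides`, `normalize_stride`, `posthoc_auto`,
   `rm_anova`, `condition_vs_level`).

Because fluoroscopy recordings of this preparation are not publicly
distributable, the package also provides a forward-kinematic gait generator
(`make_gait_template`, `simulate_trial`, `make_two_view_rig`,
`synthesize_features`) that reproduces the published walking conditions with
full ground truth, so the whole chain can be validated by closed-loop
recovery instead of against raw recordings.

# Models and conventions

## Landmark regression

Each landmark's pixel position in each view is predicted by a scalar linear
ε-support-vector regressor: minimize
$$\tfrac12\lVert\omega\rVert^2 + C\sum_i(\xi_i + \xi_i^*)$$
subject to $|y_i - \langle\omega, x_i\rangle - b| \le \epsilon + \xi_i$,
$\xi_i, \xi_i^* \ge 0$, over the $M$ annotated frames, where $x_i$ is the
concatenated two-view feature vector. Four scalar models per landmark
(u and v in both views) share one handle; the model is deliberately linear
and kernel-free. The solver is a sequential-minimal-optimization (SMO)
iteration on the dual in $\beta_i = \alpha_i - \alpha_i^*$, with
second-order (gain-maximizing) working-set selection and an exact piecewise
quadratic line search across the $\ell_1$ kinks; the first-order
maximal-violating-pair rule needs orders of magnitude more iterations on the
nearly singular Gram matrices that smooth gait trajectories produce. The KKT
stopping tolerance defaults to 1e-8. Correctness is cross-checked in the
test suite against libsvm (`e1071::svm`) on small random instances: the
package's objective never exceeds the reference objective and agrees with it
to the reference's own stopping precision.

Defaults are C = 1 and ε = 0.1 px, sensible for noisy annotations. For
noiseless synthetic recovery runs the package uses C = 1e6 and ε = 0.01 px —
the hard-budget regime in which training residuals are pinned inside the
tube.

## Two-view reconstruction

Each view is the 11-coefficient direct linear transformation
$$u = \frac{a_1X + a_2Y + a_3Z + a_4}{c_1X + c_2Y + c_3Z + 1},\qquad
  v = \frac{b_1X + b_2Y + b_3Z + b_4}{c_1X + c_2Y + c_3Z + 1},$$
fitted by linear least squares from at least seven non-coplanar
calibration-cube spheres (two equations per sphere, eleven unknowns).
Coordinates are centred and scaled before solving, for conditioning; the
unnormalized solve agrees within tolerance and is available as an option.
Triangulation solves the four linear equations per landmark by least squares
and records per-view reprojection errors. No lens-distortion refinement is
attempted (recordings are undistorted upstream of this package), no bundle
adjustment, never more than two views. Landmarks missing in either view stay
missing — no interpolation happens in this module.

## Anatomical frames and angles

The pelvis frame sits at the centroid of the two hip joints and the pelvis
cranial marker: $\vec e_y \propto h_l - h_r$; an interim x axis points from
$h_r$ to the cranial marker; $\vec e_z$ = interim-x × $\vec e_y$;
$\vec e_x = \vec e_y \times \vec e_z$. The whole-leg frame sits at the femur
midpoint: $\vec e_z \propto h_i - k_i$, the interim x axis runs from the
distal tarsometatarsus marker to the knee, and $\vec e_y$ (the plane normal)
completes it. Relative orientations are decomposed with the Cardan sequence
z–x–y, read as intrinsic rotations applied z, then x, then y
($R = R_z R_x R_y$): this is the reading under which z is ab-adduction,
x axial/mediolateral rotation and y flexion–extension, self-consistent with
the frame definitions; it is enforced by recomposition tests (error < 1e-9
over 1000 random rotations). In the zero pose the femur is orthogonal to
the pelvis, so hip flexion–extension is reported as β + 90°. Right-leg z and
x angles are negated so both legs share the left-leg sign convention. The
same z–x–y sequence is used for the pelvis against the global frame (pitch
β, roll α, yaw γ; negative pitch = retroversion); whether the original
analysis used the same sequence for the pelvis is not documented, and this
choice is flagged here. Near gimbal lock (|α| within 0.5° of 90°) the
decomposition warns and lets γ absorb the indeterminacy; it never silently
wraps.

Knee, INT and TMP are three-dimensional included angles rather than sagittal
projections; for the quasi-sagittal gaits simulated here the difference is
small, and the convention is a deliberate, documented choice. The effective
leg runs from the hip to the middle-toe tip; its angle α is measured in the
global sagittal (x–z) plane from the forward horizontal, below 90° when the
toe is cranial to the hip, so level touchdown sits near 43° and toe-off near
108°. Velocities use 2nd-order central differences after an optional
4th-order zero-phase Butterworth low-pass at 25 Hz (mean removal plus
odd-reflection padding suppress the filter's edge transients).

## Stride machinery

Strides are trailing-limb TD→TD and leading-limb TO→TO around the terrain
shift, and same-leg TD→TD on level trials; every variable is linearly
interpolated to 100 phase points (indexing is 0-based over 0..99, so the
"15 %" event is index 15). Analysis windows cover the event ± 4 samples;
windows truncated by the curve boundary are flagged rather than wrapped.
Event detection declares contact while the toe stays within `height_thresh`
of a rolling-minimum ground baseline, with a 10-frame hysteresis. The
default threshold (1e-5 m) is matched to the generator's exact substrate
contact; digitized event tables always take precedence and are what real,
noisier recordings should use. A toe-speed gate exists but is off by
default: the generator's stance toe rolls slowly forward (see below), as
real toes do, so a strict stationarity gate would truncate stance.

## Statistics

Variance homogeneity is tested with the Brown–Forsythe (median-centred)
Levene statistic; homogeneous groups get TukeyHSD (Tukey–Kramer for unequal
n), heterogeneous groups Games–Howell with per-pair Welch degrees of
freedom — for two groups Games–Howell reduces exactly to Welch's t-test,
which the test suite verifies to 1e-6 over 100 random instances. Condition
versus level is a one-way MANOVA over the 9-sample event window (the
original report does not specify the multivariate response; a univariate
comparison of window means is the config-switchable alternative and supplies
the reported p-value and star code either way). Repeated-measures ANOVA for
the step conditions uses `aov` with an `Error(id/...)` stratum after
listwise completion, with Greenhouse–Geisser correction reported by default
(the original analysis is silent on sphericity). No multiple-testing
correction is applied across variables beyond the post hoc family, mirroring
the original reporting.

# The gait generator

## What it emulates

`make_gait_template` encodes the seven study conditions (level, up/down ×
1/2.5/5 cm) as control-point tables at the stride phases TD, 15 %,
mid-stance, TO and late swing, populated with the published event values:
level speed 0.65 m s⁻¹, hip flexion–extension 42° at TD extending 17° to
57° at TO, mediolateral rotation −14° → 11°, abduction 36° → 18°, knee 120°
at TD, effective-leg angle 43° at TD and 108° at TO, pelvic retroversion
10°, aperture 53° at contralateral touchdown, and the condition-specific
overrides for the step templates. Control points are interpolated with
periodic cubic splines (value and slope continuous across the stride
boundary); step-stride overrides use the same machinery with the condition's
duty factor. Pelvic pitch oscillates at twice the step frequency (amplitude
2°), roll at the step frequency (3°), yaw at the stride frequency (2°) —
the oscillation amplitudes, pelvis height and step width are not reported
numerically anywhere, so these are generator defaults stated here and in the
configuration, not values asserted against the literature.

## Hybrid prescription

A purely joint-driven forward model cannot simultaneously reproduce the
published hip angles, effective-leg values, speed and stride timing, because
those quantities are mutually coupled through ground contact. The generator
therefore prescribes, per frame:

- the pelvis pose (constant forward speed; oscillations as above),
- the hip Cardan angles (so the whole-leg frame recovers them exactly),
- the knee included angle,
- the effective-leg sagittal angle α,

and derives the rest from two constraints: during stance the toe lies on the
substrate (z = 0, which fixes the effective-leg length as
$l = z_{hip}/\sin\alpha$ — with hip height $0.13\,\sin 43° = 0.0887$ m this
reproduces the published l = 0.13 m at TD *and* l ≈ 0.093 m at TO with no
further tuning, a consistency check on the published values themselves);
during swing the toe follows a C1 clearance bump
$16\,s^2(1-s)^2 \times 0.017$ m over the swing fraction s, so toe height
and vertical velocity are continuous at both events. The intertarsal and
TMP joints close the chain by planar two-link inverse kinematics inside the
leg plane, which keeps every segment rigid to machine precision. Where a
step condition's prescribed geometry would leave the two distal segments
unable to span the intertarsal-to-toe gap, the knee yields by the smallest
angle that restores reach — knee values between the published events are
interpolation, not data.

One stance consequence is deliberate: the toe's ground point slides about
2.5 cm cranially over stance. This stands in for the rolling contact of a
real foot and is what reconciles the printed speed (0.65 m s⁻¹), stride
time (0.37 s), angle of attack and leg lengths; a fixed point of rotation
cannot satisfy all four.

## Calibration of the aperture control

All stance controls of the level effective-leg angle except the mid-stance
one are pinned by published values. That one free control point is set by a
deterministic 1-D root search (`calibrate_aperture`) so that the
three-dimensional aperture angle between the two effective legs equals 53°
at contralateral touchdown. This is part of template construction, not a
fit to data: it implements the published "fixed aperture" observation as a
generator property.

## Synthetic features

The out-of-scope CNN feature extractor is replaced by a pluggable contract:
any map from a frame pair to a D-vector. The default synthetic source
standardizes the 88 two-view landmark coordinates, applies a fixed random
affine map that is injective on the signal subspace (D = 192 by default),
appends 8 bounded nonlinear distractor channels, and adds Gaussian channel
noise (default 1 % of the standardized signal). Noiseless features make
exact linear recovery possible in principle; how many annotated frames that
takes depends on the intrinsic dimension of the motion. Over one simulated
stride the 88-coordinate trajectory has ≈ 12 effective dimensions (principal
components beyond the ninth still carry ≈ 0.75 px RMS), so the recovery
experiment annotates M = 15 equidistant frames (held-out error ≈ 0.4 px);
with 10 frames — sufficient for the compressed CNN features the original
method was built around, and still the tracking default — min-norm linear
interpolation leaves 2–3 px of held-out error on these raw-coordinate
features.

# Validation: what passing tests do and do not show

The acceptance experiment runs the entire chain — simulate one level stride
at 500 Hz, project it noiselessly through the synthetic biplanar rig
(optical axes ≈ 90° apart, ≈ 0.6 mm px⁻¹ at the subject), synthesize
noise-free features, track from 15 annotated frames, calibrate the DLT
cameras from a 27-sphere cube, triangulate, analyze — and compares the
recovered values with the published ones: hip flexion–extension 42° at TD,
17° extension excursion, abduction 36°/18° at TD/TO, mediolateral 11° at TO,
stride-mean pelvic retroversion 10°, aperture 53° at leading-leg TD, speed
0.65 m s⁻¹. Everything lands within the 1° interpolation-plus-event-
discretization budget (typically within 0.3°). Property suites back the
individual stages: Cardan recomposition ≤ 1e-9 over 1000 rotations,
noiseless project–triangulate round trips ≤ 1e-9 m, SVR-versus-libsvm
objective agreement, Games–Howell/Welch equivalence, familywise type-I error
within [0.03, 0.07] over 2000 null simulations, and mirror-trial identity.

What this does **not** show: robustness to the failure modes of real
fluoroscopy — soft-tissue occlusion, marker mis-identification, image
distortion residuals, non-Gaussian annotation error, and features whose
relation to landmark position is far from affine. The generator's distal
joints are a geometric closure: realistic at the analyzed events, but
over-folded mid-swing (the TMP included angle dips to ~20° on level strides
and further in step conditions, where real birds fold mainly the
intertarsal joint). Pelvis height, step width and the pelvic oscillation
amplitudes are plausible defaults, not measurements. Conclusions about real
birds should rest on the published recordings; the synthetic suite
establishes that the *analysis chain* is correct, deterministic and
self-consistent.

# Numerical choices

- Spline interpolation: `stats::spline` periodic for full-cycle curves,
  natural for part-cycle tables.
- SMO: KKT tolerance 1e-8, iteration cap 2e5 with a reported residual on
  non-convergence; feature channels standardized with training-frame
  statistics (stored in the model).
- DLT: normalization on by default; calibration refuses < 7 spheres or a
  coplanar cloud; triangulation warns on near-parallel rays (condition
  number > 1e8).
- Gimbal lock: warned at |α| within 0.5° of 90°, γ absorbs the split.
- Event detection: height threshold 1e-5 m over a 51-frame rolling-minimum
  baseline, 10-frame hysteresis, speed gate off by default.
- Degenerate inputs: collinear frame points, zero-length segments,
  all-missing strides, < 2 samples per group and unknown conditions all
  raise errors naming the violated requirement.

# Problem sizes

The default test and validation runs use one to three strides at 500 Hz
(185–555 frames, 22 landmarks), a 27-sphere cube, 2000 null simulations for
the type-I check and 100–1000 property-test instances — sizes chosen so the
full suite documents the package's behaviour in a couple of minutes on one
core while still exercising every code path at the study's native sampling
rate.
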