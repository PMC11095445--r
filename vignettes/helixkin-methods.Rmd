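---
title: "Methods: kinematics of spinning and helical swimming in salp chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics of spinning and helical swimming in salp chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixkin)
```

## The problem

Colonial salps swim as linear chains of jet-propelled zooids. Field stereo
video of such chains shows two colony-level gaits: *spinning*, where a short
chain translates along a straight path while rotating about its own axis,
and *helical (corkscrew) swimming*, where every landmark of a longer chain
traces a circular helix about a straight displacement axis; intermediate
chains divide their time between the two. The gait arises mechanically: each
zooid's excurrent siphon is tilted obliquely relative to the chain axis, and
because zooids share only chiral (not rotational) symmetry with their serial
neighbors, the tangential components of the jet reaction forces do not
cancel — the chain receives net axial thrust plus a net torque about its
axis.

`helixkin` implements the measurement side of this story — motion-corrected
3D trajectory analysis, spin and helix kinematics, swimming-mode
classification, siphon/jet angle statistics, jet Reynolds numbers — together
with a minimal rigid-chain multi-jet wrench model of the torque mechanism
and a ground-truth-labelled synthetic trajectory generator against which
every stage is validated.

## Data model and units

Input is a flat CSV of digitized landmark tracks (one row per landmark and
frame; columns `landmark_id, role, zooid_index, frame, x, y, z`), with a
JSON sidecar for colony metadata. Coordinates are mm, time seconds, angles
degrees in files; phase arithmetic is done in radians internally. Landmark
roles form a controlled vocabulary: `zooid_gut` (the tracking landmark for
each zooid), `reference_particle` (a passive drifter), `off_axis_marker`
(e.g. an unreleased fecal pellet on a zooid's edge, used to measure spin),
`siphon`, and `jet_trace`. Frames may be missing per track — manual
digitization has gaps — and joint operations work on frame intersections,
counting what they drop. The digitization frame rate is a required user
input (it is a property of the digitization, not of the package).

## Motion correction

Background motion of water, diver and camera is removed by subtracting, per
frame, the coordinates of a co-tracked passive reference particle. The
subtraction is exact for any additive motion shared by animal and
reference; this is tested as a property (random drift series leave every
motion-corrected coordinate unchanged to below 1e-9 mm). No temporal
smoothing of the reference is applied by default, and missing reference
frames are dropped rather than interpolated; both behaviours are available
as explicit, logged options. Correction precedes every other computation in
the pipeline.

## Chain axis, rotation phase, and the handedness convention

The chain axis at a frame is the line through the zooid-gut landmarks: with
two guts, the line through them; with three or four, the total-least-squares
line (first principal direction of the centered points).

"Clockwise" is meaningless without a viewpoint — two observers of the same
2D sequence can perceive opposite rotations (the spinning-dancer ambiguity),
which is why 3D stereo information is needed at all. The package fixes one
convention and stamps it on every result object:

> CW/CCW viewed looking along the swim direction from behind the colony;
> positive angular velocity = CCW (right-hand rule about the axis), so
> positive angular frequency corresponds to a right-handed helix.

Concretely, the axis direction is oriented along the colony's net
displacement, and the in-plane basis `(e1, e2)` is right-handed about it.
The rotation phase of an off-axis marker is its polar angle in that plane,
unwrapped over time. When the instantaneous axis is re-fitted per frame, the
in-plane basis is parallel-transported between frames by the *minimal
(zero-twist) rotation* taking each axis direction to the next, so axis
wobble cannot masquerade as spin. (A transport built from frame-to-frame
axis-point displacements was rejected: at 100 fps those displacements are
dominated by digitization noise and inject large random twist; the
axis-angle transport uses directions only and leaves phase-slope errors
below 0.5% at 0.2 mm noise.)

Angular velocity is the finite difference of unwrapped phase,
`omega_i = (theta_{i+1} - theta_i)/(t_{i+1} - t_i)`. Two summaries are
reported: `mean(|omega_i|)` — the classical per-step definition — and the
median of `omega_i`. The mean of absolute steps is positively biased
whenever the true per-frame phase step is comparable to the phase noise
(folded noise), so for slow rotations the median is the number to trust;
the pipeline reports both. Handedness is the sign of the median under the
convention above, with a configurable significance floor below which the
direction is reported `indeterminate` rather than guessed. Sampling must
resolve the rotation (`|omega| * dt < pi`); near-Nyquist phase steps raise
an error instead of silently aliasing.

## The helix model and its estimator

A motion-corrected trajectory is modelled as a circular helix

x(t) = c + (a0 + v t) u + R [cos(w t + phi) e1 + sin(w t + phi) e2]

with unit axis `u`, orbit radius `R` (mm), signed angular frequency `w`
(rad/s), axial speed `v` (mm/s), and pitch `2 pi |v| / |w|` (mm per turn).

`fit_helix()` is a two-stage estimator:

1. **Axis.** Among the three principal directions of the centered point
   cloud, the axis is the one minimizing the spread of radial distances:
   the first principal direction for straight tracks and long helices, the
   plane normal for near-planar (low-pitch) orbits. It is oriented with the
   net displacement.
2. **Cylindrical regression.** About that axis, `R` is the mean radial
   distance, `w` the slope of unwrapped polar angle versus time, `v` the
   slope of the axial coordinate versus time.

A joint Levenberg-Marquardt refinement of all nine parameters follows by
default (the axis direction is parameterized as a normalized perturbation of
the stage-1 direction, which is smooth and free of gimbal problems; the
axis point is constrained to the perpendicular plane through the centroid,
its axial position being absorbed by `a0`). The refined parameters are kept
only if they do not increase the RMS residual, so refinement can never
degrade the initializer. On noiseless synthetic helices the refined fit
recovers radius, pitch and angular frequency to better than 1e-6 relative
error; the two-stage initializer alone is limited by the slight tilt of the
principal axis on finite samples.

Degenerate inputs are handled explicitly:

- **Straight trajectories** (radial excursion within `3 * sd` of the
  scatter) return a *non-rotating* fit: measured orbit radius, pitch and
  angular frequency `NA` — pitch is undefined where there is no orbit, and
  is reported as not-applicable rather than zero.
- **Near-planar circular orbits** (no axial progress) are fit as helical
  with pitch near 0 and flagged `planar`; the handedness sign is not
  meaningful without a displacement direction.
- A trajectory at a **static offset** from the chain's axis is, about its
  *own* displacement axis, simply a straight track, and is returned as a
  non-rotating fit. A defensive error (`hk_non_rotating_orbit`) guards the
  remaining corner — orbit radius well above scatter with less than a
  quarter turn of phase — though with the axis fit through the trajectory's
  centroid that geometry does not arise from generic input.

`fit_helix()` returns a classed object with the usual modelling methods
(`print`, `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`,
`simulate`).

## Swimming-mode classification

The field coding rule is orbit radius 0 (spinning) versus greater than 0
(helical), which is unusable verbatim under measurement noise. The package
uses:

- **Threshold.** `tau = max(0.25 * zooid_length, 3 * noise_floor)` mm,
  where the noise floor defaults to the median RMS residual of the window
  fits. The first term scales with animal size (zooids are ~10 mm), the
  second keeps the threshold above the measurement noise. `tau` is
  configurable and always echoed in reports.
- **Windows.** Fixed-duration windows of two estimated rotation periods
  with 50% overlap — long enough for a stable per-window helix fit, short
  enough to resolve transitions. The period is estimated robustly as the
  median per-step phase rate over samples well off the axis; when no
  rotation is detectable (or the implied window would hold too few
  samples), a quarter of the record is used, which only matters for records
  that classify spinning throughout.
- **Recording level.** Spinning if at least 80% of the windowed duration is
  spinning, helical if at least 80% helical, otherwise transition. The
  field description of "transitional" chains gives no numeric rule; 80% is
  an explicit, configurable surrogate.

On synthetic data this classifies noiseless spinning, helical, and
half-and-half transition recordings correctly under the defaults, and
reproduces the qualitative size effect (chains generated with more zooids
and larger orbit radii classify helical; short straight spinners classify
spinning). That is a property of the classification rule, not a recovery of
field group means, which depend on the wild population.

## Angle metrics

All zooid, siphon and jet angles are *unsigned acute* angles to the chain
axis, `acos(|v . u| / |v||u|)` folded into [0, 90] degrees, matching how
such angles are reported (e.g. dorsoventral zooid tilts near 22 degrees);
a 2-vector branch serves angles digitized in a single image plane. Angle
series statistics report max, min, mean, sample SD (n-1 denominator), and
the percent decrease `100 (max - min)/max` describing the drop of the
siphon angle during jetting; full precision is kept internally and one
decimal is shown for display. Count percentages are *truncated*, not
rounded (`floor(100 k/n)`), deliberately matching the field reporting
convention in which 10 of 15 prints as 66%.

`reynolds_number(U, d, nu)` is `U d / nu`. A note on printed values: a jet
of `U` = 0.15 m/s in seawater (`nu` = 1.05e-6 m^2/s) through a 0.3 mm
siphon gives Re of about 43, whereas Re of about 429 requires a diameter
near 3 mm. Published figures quoting both a 0.3 mm diameter and Re = 429
with these U and nu are internally inconsistent by a factor of ten; the
package implements the formula, documents the discrepancy, and does not
decide which printed value is the misprint.

## The multi-jet wrench model

The torque mechanism is quantified by statics on a rigid chain:
`jet_spec` objects carry an attachment point (the excurrent siphon), a unit
efflux direction, and a magnitude in consistent model units (no thrust
calibration is attempted); the thrust on the body is minus the efflux.
`net_wrench()` sums forces and moments about the chain axis:
`axial_thrust = u . sum(F_i)` and
`axial_torque = u . sum((p_i - c) x F_i)`, with the predicted handedness
read from the torque sign under the same viewing convention as the
kinematics, so model and measurement are directly comparable.
`build_chain_jets()` constructs an idealized chain: uniform axial spacing,
attachments alternating dorsal/ventral (chiral, not rotational, symmetry),
each jet tilted dorsoventrally in the radial plane and laterally in the
tangential plane with a common tangential sense. Purely dorsoventral tilt
produces no axial torque (the force lines stay in radial planes); any
common-sense lateral tilt does. The thrust-to-torque ratio of a tilted jet,
`cos(theta)/(r sin(theta))`, decreases strictly with tilt — the quantitative
form of "low-angle jets maximize thrust and minimize torque". The lever
radius is a free model parameter (it is not reported in field data; 5 mm,
half a zooid length, is the default). The model is instantaneous statics
only: no drag, added mass, rotational dynamics, jet-jet interaction, or
buckling of long chains.

## The synthetic generator

The generator produces the statistical structure the analysis assumes, with
ground truth attached:

- **Spinning**: gut landmarks on a straight line translating at constant
  velocity; one off-axis marker rotating about that line; a passive
  reference particle.
- **Helical**: gut landmarks on circular helices of common radius, pitch
  and signed angular frequency about a straight axis, phases staggered by
  the axial zooid spacing.
- **Transition**: a spinning segment spliced to a helical segment,
  positions continuous at the switch (the helical axis is placed parallel
  to the swim axis at one orbit radius from the gut line, and each landmark
  starts its helix from its own switch position), with per-window
  ground-truth labels.
- **Siphon series**: `mean + amplitude cos(2 pi t / period)` plus noise,
  clamped into [0, 90] degrees (with the default small noise the clamp is
  rarely active).

Background drift (added identically to animal and reference tracks) is a
constant velocity plus a low-frequency sinusoid; digitization noise is
i.i.d. isotropic Gaussian per coordinate. Defaults are the package's
standard study conditions: 100 fps, 3 s records, mean axial speed
178.8 mm/s, default rotation rate 2.83 rad/s (162 degrees/s — a reported
rotation rate of "162 radians per second" would mean ~26 revolutions per
second for a centimetre-scale chain, which is implausible; the package
treats the plausible reading as degrees per second and always labels
units), orbit radius 10 mm for helical motion, zooid spacing 4 mm
(a 153 mm chain of 39 zooids), zooid tilt angles 22.3 (dorsoventral) and
22.2 (lateral) degrees, and noise sigma 0.5 mm (~5% of a zooid length; no
field estimate of digitization error exists, so this is a documented
assumption). All generators are deterministic given their seed and restore
the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: body flexibility and undulation (the generated chain
is rigid), pulsatile within-cycle acceleration (translation is steady),
non-Gaussian or temporally correlated digitization error, reference
particles that are themselves motile, and partial occlusion patterns beyond
simple missing frames.

## Numerical choices

- Phase unwrapping removes 2 pi jumps assuming the true step is below pi;
  under-sampled rotations error out rather than alias.
- The LM refinement runs at most 100 iterations and is accepted only if the
  RMS residual does not increase; a negative fitted radius is folded into a
  phase shift of pi.
- Ties and degeneracies: coincident landmarks, zero vectors, empty frame
  intersections, and single-sample inputs raise classed errors
  (`hk_degenerate_geometry`, `hk_alignment_error`, ...) rather than
  returning quiet numbers.
- Axis orientation with single-frame data (no displacement available)
  points from the rear of the chain toward the frontal zooid; an explicit
  `orient` argument overrides.

## Problem sizes

The shipped tests and the acceptance script use 2-6 s records at 100 fps
(200-600 frames per track), 500-seed Monte-Carlo sweeps for parameter
recovery (0.2 mm noise), 100-fold random-rotation suites for chirality, and
1000 randomized jet sets against a brute-force wrench oracle; the full
suite runs in well under a minute on one core. These sizes give the
Monte-Carlo assertions comfortable margins (observed median recovery errors
are ~0.2% against a 5% bound).

## Limitations

The package analyzes trajectories of digitized landmarks; it does not do
stereo calibration, triangulation, image processing, PIV, or volumetric
reconstruction. Group summaries and the one-way ANOVA are standard
reporting utilities, not contributions. The wrench model predicts the sign
and scaling of the axial torque, not rotation rates — coupling torque to
observed angular velocity would require drag and added-mass terms that are
deliberately out of scope.
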