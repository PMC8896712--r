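---
title: "Methods: simulating retinal optic flow during gaze-stabilized locomotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating retinal optic flow during gaze-stabilized locomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinalflow)
```

## The model

The package simulates the visual motion incident on the retina of a
walker who stabilizes gaze on a point on a flat ground plane while the
eye translates through space. The eye is a sphere (default radius 12 mm,
the anatomical average) with a pinhole pupil at one pole and the fovea at
the opposite pole. Each frame the eye is oriented so the pupil–fovea axis
passes through the fixated ground point; ground points are projected
through the pupil onto the back of the sphere; and the frame-to-frame
displacement of each projected point is the retinal flow. The flow is
interpolated onto a regular retinal grid and its divergence and curl are
computed, yielding the features that encode heading relative to gaze.

Key assumptions, shared with the study design this reproduces:

- the ground is an infinite flat plane at height zero (no terrain
  parallax structure);
- fixation is perfect between perturbations: the gaze ray is pinned to
  the fixated ground point, so flow at the fovea is exactly null;
- ocular torsion is held at zero (see the torsion convention below);
- the scene is static; all retinal motion comes from the eye's own
  translation and stabilizing rotation.

## Coordinates and sign conventions

The world frame is x-right, y-forward, z-up. Retinal positions are polar
(ϑ, ρ): ρ is the great-circle distance from the fovea in degrees of
visual angle, ϑ the angle from the eye's transverse-plane equator. For
planar calculus the retina is flattened by the azimuthal-equidistant
chart `x = ρ cos ϑ, y = ρ sin ϑ`.

Two conventions are fixed once and used everywhere:

- **Chart orientation.** The chart is drawn in the orientation retinal
  maps are reported in: upper visual field at the top (ϑ = π/2) and the
  *left* visual field at ϑ = 0. On this chart, fixating a point to the
  left of the travel path gives positive foveal curl and fixation to the
  right gives negative curl — the sign convention used when this cue is
  reported in the field. On a chart with x toward the right visual field
  every curl value changes sign (the flow that looks counter-clockwise on
  one chart looks clockwise on the other); fixing the handedness at the
  chart level keeps the curl field, the foveal-curl feature and the
  canonical vector-field operators (where counter-clockwise is positive)
  mutually consistent.
- **Torsion.** The zero-torsion reference is the horizontal direction at
  the gaze's own azimuth: the eye yaws to the fixation azimuth, then
  pitches down to the fixation point along the geodesic, so the eye's
  equator stays horizontal (gravity-referenced). This definition is
  equivariant under rigid motions of the ground plane — rotating and
  translating the whole scenario leaves all retinal coordinates unchanged
  — and its single degenerate configuration is straight-down gaze, where
  the azimuth is undefined and the equator direction is carried over from
  the previous frame. It is one admissible reading of "minimal torsion";
  a Listing's-law eye would differ for oblique gaze, and no mobile
  tracker measures torsion to adjudicate.

Because the pupil is a single point, the retinal coordinates of a ground
point reduce to the direction of its incoming ray: ρ equals the angle
between the ray and the optic axis (the explicit sphere-intersection
construction gives the same value — the inscribed angle at the pupil is
half the central angle of the retinal arc — and is kept as a test
oracle). This also makes projection exactly independent of the eye
radius, which the test suite asserts at 1e-9. The pose's position field
is accordingly interpreted as the optical station point (the pupil); for
ground points at metre range the 12 mm offset to the sphere's geometric
center is below a tenth of a degree and has no bearing on any feature.

## Scene sampling and interpolation

The flow must be evaluated on a regular retinal grid (default 1° spacing
out to ρ = 60°, the field-of-view radius). Scene points are sampled
*retinally*: at each frame, the rays of a half-offset copy of the
analysis lattice are cast to the ground, giving a static scene point per
lattice cell, which is then re-projected under the previous frame's pose.
This keeps the sample density uniform on the retina. A fixed ground grid
(default 0.25 m spacing) is available as an alternative
(`sampling = "ground_grid"`), with stable point ids for re-entry
bookkeeping; note that 0.25 m subtends 5–8° near the fovea at
metre-range fixation distances, far coarser than the retinal grid, so
fine foveal structure (the iso-contour degeneracy in particular) is only
resolved in the retinal sampling mode. Points not visible on the
previous frame carry undefined flow and are excluded for that frame; the
first frame's flow is defined to be zero. Ground sampling is clipped at
20 m from the eye by default — frames whose field of view reaches the
horizon would otherwise need an unbounded grid — which masks only the
far-peripheral rim of the retinal grid.

The fixated ground point itself is always included as a sample. During
perfect fixation its flow is exactly zero, which anchors the foveal null
(the suite asserts foveal speed < 1e-6 deg/s); during a slip or saccade
its displacement equals the gaze sweep exactly, which anchors the
perturbation speed measurements.

Scattered samples are interpolated with a locally weighted linear
(moving least squares) fit: at each node a plane is fitted through the
samples within a search radius (2.5 grid spacings by default) with
smooth `(1 - (d/r)^2)^2` weights. The scheme is exact for fields linear
in position, takes the sample value exactly at a node that coincides
with a sample, and masks nodes outside the convex hull of the samples
rather than extrapolating — flow is undefined where nothing was
visible. A Delaunay-based piecewise-linear interpolant would share these
properties; the weighted-linear fit was chosen because it is robust to
the highly collinear point patterns that symmetric scenes project, and
needs no triangulation library.

## Divergence, curl, and the chart metric

Divergence and curl are computed with central differences on interior
nodes and one-sided differences at boundaries and next to masked nodes;
both are exact for fields linear in position, which is what makes the
canonical fields evaluate to exactly 2 at every node including the
edges. Positive curl is counter-clockwise on the chart.

The equidistant chart compresses azimuthal distances by `sin ρ / ρ`, so
purely planar operators applied to retinal fields acquire an error that
grows with eccentricity. The package therefore applies the first-order
metric correction by default (`metric = "spherical"` in `flow_frame()`):

- `div_s = div_chart + u_ρ (cot ρ − 1/ρ)`
- `curl_s = curl_chart + u_φ (cot ρ − 1/ρ)`

Both corrections vanish at the fovea, so foveal features are identical
under either setting. The correction matters for the divergence maximum,
which sits tens of degrees below the fovea: with planar operators the
angle between the maxdiv direction and the velocity direction acquires a
systematic ~15 % multiplicative bias (0.17° per degree of fixation
offset, independent of grid resolution); with the correction the
velocity-through-maxdiv law holds to better than 0.1° across a ±10°
offset sweep and the regression of the maxdiv/fixation angle on the
velocity/fixation angle has unit slope. `metric = "planar"` reproduces
the uncorrected behaviour of standard planar `divergence`/`curl`
routines.

## Features

- **Foveal curl** — mean of the curl field over nodes with ρ ≤ 2°
  (window configurable). Zero at machine precision when fixation is
  aligned with the velocity; sign equals the fixation side; magnitude
  strictly increasing in the offset over the tested ±10° range.
- **Divergence maximum** — argmax over valid nodes (ties broken toward
  the fovea, since the foveal iso-contour contains the peak), refined by
  a quadratic fit over the 3×3 neighbourhood when the neighbourhood is
  fully valid and concave; flagged `boundary` otherwise. Its ground
  back-projection lies on the eye's velocity line (within one ground-grid
  spacing; directionally within 0.1°).
- **Foveal iso-contour** — the divergence level set at the foveal value,
  extracted by marching squares with the level nudged by 1e-8 of the
  field range toward the peak side so the level set is well defined at a
  node value. The connected component enclosing or touching the fovea is
  returned; `degenerate` when its enclosed area is below one grid cell
  (or when the level set has receded from the fovea entirely, i.e. the
  peak is at the fovea), `open` when it runs into the masked rim. During
  the canonical straight approach (eye height 1.25 m, speed 1.25 m/s,
  start 5 m out, 60 fps) the contour closes, constricts, and first drops
  below one grid cell at a gaze declination of 45.0° — the one-eye-height
  moment — then reopens into the upper field.
- **Heading angles** — signed angles at the eye's ground position,
  positive when the reference direction passes right of the fixation
  point: `velocity_fixation_angle` uses the ground-projected velocity,
  `maxdiv_fixation_angle` the direction to the maxdiv ground point.

## Perturbations

Slip and saccades are modelled as sweeps of the gaze ray away from the
scheduled fixation point, in a stated retinal direction: uniform over the
window to a stated total magnitude for slip (fixation-point drift, the
gain-below-one analogue), at a stated rate for a saccade. The per-frame
fixation becomes the ground intersection of the swept ray; one frame
after the window the gaze returns to the schedule, and all frames whose
flow pair overlaps the window (including that return frame) are flagged
`perturbed`, so a frame-wise diff against the unperturbed run differs
only on flagged frames.

For a standing observer the measured foveal image speed is exactly the
sweep rate: 1° of slip over 250 ms gives 4.000 deg/s, a 195 deg/s
saccade gives 195.000 deg/s. During forward locomotion a second-order
term appears: mid-saccade the gaze is no longer on the fixated point, so
the ground flow at the instantaneous fovea is no longer nulled and adds
a counter-component that grows with walking speed and accumulated sweep
(≈2 % at 1.25 m/s for a 0.05 s saccade, ≈0.8 % at 0.5 m/s). The
acceptance measurement of the saccade speed therefore uses a slow
(0.5 m/s) approach at 120 fps, where the residual stays below the 1 %
measurement tolerance; the effect itself is real and documented rather
than subtracted.

Two further properties of injected perturbations are worth noting.
First, the added flow of a downward slip is bounded by the foveal slip
speed everywhere on the retina (asserted in the suite); a slip with a
lateral component can exceed that bound by up to ~35 % in the far
periphery, because changing the gaze azimuth under the gravity-referenced
torsion convention rotates the eye about the gaze axis and the chart
stretches azimuthal motion. Second, an injected saccade multiplies the
median flow speed and the median curl magnitude by well over an order of
magnitude, but barely changes the divergence field (×1.1–1.5): a rigid
rotation is divergence-free, so over a flat ground plane the
order-of-magnitude divergence changes seen in camera-based flow of real
terrain do not reproduce in the geometric model.

## Synthetic trajectories

The generators emit the same pose tables the pipeline consumes, with the
statistical structure of walking data. Parameters and defaults:

| generator | parameter | default | meaning |
|---|---|---|---|
| all | `eye_height` | 1.25 m | standing eye height of the simulated walker |
| `straight_approach` | `speed` | 1.25 m/s | comfortable walking speed |
| | `start_distance` | 5 m | ground distance to the fixated point at t = 0 |
| | `fixation_offset_angle` | 0° | signed angle of fixation off the travel direction (positive = left) |
| `gait_head_trajectory` | `step_frequency` | 2 Hz | natural footstep rate |
| | `vertical_peak_vel_fraction` | 0.5 | peak vertical head velocity over walking speed |
| | `lateral_peak_vel_fraction` | 0.2 | lateral sway (at half the step rate, alternating feet) |
| | `gaze_distance`, `fix_duration` | 3 m, 1 s | re-fixation schedule |
| `synth_calibration_session` | `calib_distance` | 1.4 m | ground marker ahead of the subject |
| | `amplitude` | 20° | head sweep amplitude (pitch, yaw, both diagonals) |
| | `truncation_distance` | 10 m | endpoint for gaze rays that miss the ground |

The gait model is a two-harmonic sinusoid, not a biomechanical model: it
targets exactly the two statistics the study states — a 2 Hz spectral
peak of the vertical head velocity, with peak magnitude half the walking
speed (both held to 2 % across walking speeds 0.8–2.0 m/s in the suite) —
plus a smaller lateral sway. It does not reproduce full gait-cycle
acceleration waveforms, double-support asymmetries, or head rotation;
passing tests say nothing about those. Eye height defaults to 1.25 m (a
standing adult's order of magnitude; the study reports subject heights
but not eye heights) and walking speeds are declared assumptions, since
the study does not state the speeds used in its simulated conditions.
Synthetic calibration sessions place the true gaze on the calibration
point every frame and corrupt the *sensor-frame* gaze by the inverse of
the misalignment under test plus optional isotropic angular noise; real
sessions additionally contain tracker drift, blinks and head-translation
wobble that the generator does not emulate.

## Focus-of-expansion tracking

The FoE of a flow field is a repellor; negating the field turns it into
an attractor. A uniform grid of particles (default 20 × 20, seeded only
on valid cells so masked regions do not dilute the vote) is advected by
fixed-step midpoint (RK2) integration with bilinear lookup, step 0.25
grid spacings scaled by the field's maximum speed, up to 1000 steps,
terminating on grid exit or convergence. Endpoints are binned (bin =
1/20 of the field width); the detection fraction is the share of
particles within one bin of the winning bin's endpoint centroid — a
radius criterion, so an attractor that straddles a bin edge is not split
— and the FoE is `present` when that fraction reaches the majority
threshold (0.5), located at the cluster centroid for sub-bin accuracy.
FoE displacement between frames is converted to deg/s by multiplying by
(field of view / field width) and the frame rate; the conversion is a
multiplication even though one source sentence says "divided by the
framerate", which is dimensionally inverted. On synthetic radial fields
the tracker recovers 100/100 random FoE locations within one bin with
fractions above 0.9; uniform translation and pure rotation yield
`absent`; for a level constant-velocity walk the FoE sits exactly on the
horizon — the edge of the ground-visible region — so the stability tests
use a slightly descending path that puts it strictly inside the data.

## VOR calibration

Raw gaze is rotated by a candidate Euler triple (intrinsic X-Y-Z,
degrees — the convention is used consistently by the generator and the
fitter; any consistent pair works), then by the frame's head orientation,
and cast from the eye center to the ground; rays that do not intersect
are truncated at 10 m and kept in the error (truncation rather than
discarding shapes the cost surface for large misalignments). The mean
distance to the calibration point is minimized from a zero start by
Nelder-Mead with a BFGS polish. With sweeps about two or more head axes
the problem is identifiable: noiseless sessions recover the true
misalignment to well under 0.1° per axis (verified over a 3×3×3 grid of
truths within ±10°), and 0.5° of per-frame angular noise still yields
recovery within 0.5° per axis across 20 seeds. A single-axis sweep
leaves the rotation about the gaze axis unobservable and triggers a
warning instead of a fit guarantee. The verification statistic is the
RMS scatter of the intersections about their centroid: near zero at the
true alignment, two orders of magnitude larger at a 5° error.

## Problem sizes and determinism

The shipped test suite runs the pipeline at desk scale: short scenario
segments (0.15–0.6 s) for feature checks, the full 3.4 s straight
approach at 60 fps for the iso-contour constriction, 10-offset sweeps
for the heading laws, 100 synthetic fields for the FoE oracle, 27 + 21
calibration fits, and 300 random generator draws for the scenario
validity property. Everything is deterministic given the seeds fixed in
the tests; generators reproduce bit-identical scenarios for identical
seeds, and `run_scenario()` writes byte-identical feature tables for
identical configurations, together with a JSON manifest (generator,
parameters, seed, analysis settings) sufficient to reproduce a run.

## Known limitations

- The chart-planar operators are first-order corrected, not exact
  spherical differential operators; a residual of order ρ³ remains at
  high eccentricity.
- The flat-ground assumption removes all motion parallax from terrain
  structure; features over real, rough terrain will carry local
  variation this model cannot show.
- Torsion is held at zero by convention; VOR-active gaze in real walkers
  violates Listing's law in ways the model does not represent.
- The FoE tracker's step size, particle count and termination rule are
  package defaults; the tests show detection is insensitive to the seed
  density and threshold on synthetic fields, but no claim is made about
  camera-based flow of real scenes.
- Binocular geometry, lens optics, and perceptual read-out of curl or
  divergence are out of scope.
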