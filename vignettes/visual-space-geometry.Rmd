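---
title: "The geometry of perceived visual space: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geometry of perceived visual space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visualmanifold)
```

## The model

Perceived visual space is modelled as the outside world carrying the
conformally rescaled metric `g = (1/r²) ḡ`, with `ḡ` the Euclidean metric
and `r` the Euclidean distance from the egocentre (the midpoint of the two
eyes' rotation centres). The single modelling assumption is the
size–distance law of the eye's optics extended isotropically to three
dimensions: perceived lengths shrink as `1/r` in every direction, so that
receding objects shrink without changing their infinitesimal shape. All
other results in the package are theorems of Riemannian geometry applied to
this one metric.

Three consequences orient everything else:

* **Perceived distance is logarithmic.** The metric length of the radial
  segment from the 1 m sphere to distance `r̄` is `ln r̄`
  (`perceived_distance()`); inside 1 m it is negative. The lower limit of
  the defining integral is fixed at 1 m by convention, which removes the
  scale ambiguity; the model is agnostic about the perceptual status of the
  immediate peri-ocular region, so small radii are allowed rather than
  forbidden, and the radial floor appears only as an integration stop.
* **Conformality.** Metric angles equal Euclidean angles everywhere, while
  metric norms are `1/r` times Euclidean norms. This is what makes the
  binocular machinery compatible with the metric machinery: directions can
  be computed in whichever chart is convenient.
* **Visual spheres are special.** The metric is constant on spheres centred
  at the egocentre; their great circles are geodesics, they are totally
  geodesic submanifolds, and they are perceived as flat frontal planes on
  which size is determined by visual angle alone.

## Coordinate bases

Tangent vectors carry an explicit basis tag and are never coerced silently:

* *angular* — coordinate velocities `(ṙ, θ̇, φ̇)` of the spherical chart;
  metric `diag(1/r², cos²φ, 1)`;
* *tangential* — physical components along the orthonormal
  radial/azimuthal/elevational frame, `v_r = ṙ`, `v_θ = r cosφ θ̇`,
  `v_φ = r φ̇`; metric `(1/r²) I`;
* *cartesian* — `(ẋ, ẏ, ż)`; metric `(1/r²) I`.

Points with `|φ| ≥ π/2 − 10⁻⁶` are rejected at construction: the angular
metric degenerates at the poles and the angular/tangential conversion
divides by `cosφ`. This is a chart artefact, not a feature of the model;
analyses near the poles should rotate the configuration first (the metric
is rotationally symmetric about the egocentre, and the package's tests
verify this isometry).

## Two curvature computations, and why the package has both

The package deliberately exposes two distinct curvature pipelines, because
the two standard ways of organising this computation answer different
questions and give different numbers.

**The tangential-frame arrays** (`christoffel_closed_form()`,
`riemann_tensor()` with the default basis, `sectional_curvature()`) treat
the tangential components as coordinates for a metric `(1/r²) I` that
depends on the first coordinate only. This yields exactly seven nonzero
symbols, all `±1/r`, and lowered curvature components whose
symmetry-distinct nonzero set is `R₁₂₂₁ = R₁₃₃₁ = R₂₃₃₂ = −1/r⁴`.
`sectional_curvature()` contracts these arrays over Euclidean-unit spanning
pairs, so coordinate planes return the component values `−1/r⁴` themselves
("curvature per unit Euclidean area"); the scale-free identity
`K·r⁴ = −1` then holds at every radius. This is the family of numbers the
model's qualitative story is usually told with: curvature is negative in
this convention and decays rapidly with distance, which matches the visible
divergence of near-field geodesic families and its rapid weakening with
distance.

**The spherical-chart tensor** (`riemann_tensor(basis = "angular")`,
`ambient_sectional_curvature()`, and everything in the surface module) is
the coordinate-basis curvature of the metric `diag(1/r², cos²φ, 1)` that
the geodesic integrator actually integrates. Under the substitution
`u = ln r` this metric is the product of a line and a unit sphere:
`du² + (cos²φ dθ² + dφ²)`. Its normalised sectional curvature is 0 on any
plane containing the radial direction and +1 on visual-sphere planes; in
particular every plane through the egocentre is *intrinsically flat* (the
map `(r, θ) → (ln r, θ)` is an isometry of the horizontal plane onto a flat
strip). The two pipelines are genuinely inequivalent because the spray (and
hence the frame computation) is non-tensorial — re-expressing velocity
components is not a change of chart. Only the spherical-chart tensor
satisfies the Gauss relation for embedded surfaces, which is why the
surface module uses it exclusively.

Two practical corollaries worth stating plainly:

* Geodesic *divergence* in a plane through the egocentre is the linear
  spreading of straight lines in the flat `(ln r, θ)` chart, mapped through
  the exponential. Nearby geodesics do diverge, strongly so in the near
  field, without the plane being intrinsically hyperbolic.
* A geodesic triangle in such a plane has interior-angle sum exactly 180°,
  and its metric side lengths satisfy the Euclidean law of cosines with
  equality. The package's acceptance computation measures this sum by
  three boundary-value geodesic solves and reports a value at the
  180-degree bound; the strict hyperbolic inequalities (sum < 180°,
  `c² > a² + b² − 2ab cos C`) degenerate to equalities for this metric.

## Geodesics and the trajectory generator

`integrate_geodesic()` integrates the second-order system
`q̈ = f2(q, q̇)` in the angular chart, with
`f2 = (ṙ²/r, 2 tanφ θ̇ φ̇, −cosφ sinφ θ̇²)`. The θ-component was re-derived
from the variational definition of the spray (solving
`⟨g f2, w⟩ = ½⟨g'_w q̇, q̇⟩ − ⟨g'_q̇ q̇, w⟩` over basis directions `w`);
`spray_f2_variational()` keeps that derivation available as a numerical
cross-check, and the test suite asserts agreement to 10⁻⁸.

The tangential-component expression
`f2 = ((v_r² − v_θ² − v_φ²)/r, 2 v_r v_θ/r, 2 v_r v_φ/r)` is the same
geodesic field written as the *frame components of the Cartesian
acceleration* — the Cartesian-chart spray of the conformal metric. The test
suite integrates the flow in that representation too and checks that the
trajectories coincide to 10⁻⁶ over 5 s. The angular chart is the working
representation because the Cartesian form needs the frame rebuilt at every
step and behaves worse near the chart's polar singularity.

Numerical choices:

* adaptive solver (`deSolve::lsodar`) with `rtol = 10⁻¹¹`,
  `atol = 10⁻¹³`. The conservation diagnostics demand tight tolerances: the
  invariant metric speed must drift by less than a relative 10⁻⁶ over 20 s,
  and plane-confinement tests require out-of-plane excursions below
  10⁻⁸ m over 2 s; the defaults achieve ~10⁻¹¹ drift.
* root-stopping at the radial floor (10⁻⁶ m) and the polar band; a stopped
  trajectory carries a `truncated` flag rather than failing silently.
* output cadence defaults to 0.5 s, the dot spacing used in the standard
  trajectory figures.
* `geodesic_family()` launches 36 directions at 10° spacing by default with
  unit metric-norm velocities. Figure reproductions and the
  divergence-versus-distance comparison use unit *Euclidean* speed
  (1 m/s) instead: the physical reading of the figures is an object moving
  at fixed worldly speed, and with unit metric speed the family is
  self-similar in `r`, which would make near/far comparisons vacuous.

`two_point_geodesic()` shoots over the initial velocity at fixed unit
connecting time, minimising the terminal Cartesian miss. The initial guess
is constructed in the product chart (straight line in `(ln r, direction)`),
which typically lands within integrator tolerance immediately; otherwise up
to 8 seeded Nelder–Mead restarts and a BFGS polish run, and failure to reach
`10⁻⁶·|q_B|` is an explicit error. Diametrically opposed points on one
visual sphere admit a continuum of great-circle connections; the first
converged solution is returned with a `multiplicity` flag.

## Curves: transport, length, outline curvature

`covariant_derivative_along()` evaluates `∇_α̇ γ = γ' − B(α; α̇, γ)` on
sampled curves, with `B` the polarisation of the spray; with `γ = α̇` this
is the perceived acceleration (zero on geodesics; `−f2` on straight uniform
Euclidean motion — the "telegraph poles" illusory acceleration, radially
`−1/r`). Sampled-curve derivatives use central differences, so geodesic
residuals are discretisation-limited (~10⁻⁴ at 0.02 s sampling).
`parallel_transport()` integrates `γ' = B(α̇, γ)` with splined curve
interpolants; isometry drift below 10⁻⁵ over 10 s is asserted in tests.
`curve_length()` is the perceptual tape measure: composite Simpson on the
metric speed (uniform grids), trapezoid otherwise. `boundary_curvature()`
reparameterises to unit metric speed and returns
`κ(s) = ‖∇_γ̇ γ̇‖_g`; for horizontal-plane curves the flat `(ln r, θ)`
chart provides an exact independent oracle (Euclidean curvature of the
chart image), which the tests exploit.

## Embedded surfaces

A surface is a graph `r = f(θ, φ)` with analytic or finite-difference
parameter derivatives. The frame uses the Cartesian cross product of the
embedding partials (conformality makes Euclidean orthogonality metric
orthogonality), normalised to unit metric length and oriented towards
increasing `r`; flipping the orientation flips the sign of every curvature.
The scalar second fundamental form is
`h(X_a, X_b) = ⟨∇_{X_a} X_b, n⟩_g` with the spherical-chart connection of
the chosen ambient (perceived, or Euclidean for the classical limit); the
shape operator solves the g-symmetric 2×2 eigenproblem via a Cholesky
congruence. The perceived curvature `K = κ₁κ₂` satisfies the Gauss
relation `κ₁κ₂ = K̃ − K_ambient`, checked two-sidedly against an
independent intrinsic route: the Brioschi formula on the induced metric
with nested central differences (step 2·10⁻⁴ of the parameter, Richardson
extrapolated; the extrapolation is needed for patches with large
higher-order derivatives, e.g. the rim of an offset sphere). Visual spheres
come out exactly totally geodesic (`h ≡ 0`): their perceived shape is
planar, with all their curvature absorbed by the ambient term.

Shape classes follow the usual (H, K) sign table (`cap`, `cup`, `ridge`,
`valley`, `planar`, `saddle`, `symmetric saddle`) with a 10⁻⁸ zero band.
The "flattening with distance" effect is quantified in scale-normalised
units: because metric lengths scale as `1/r`, the comparable quantity is
`κ₁κ₂ / r²`, whose gap to the object's Euclidean `1/ρ²` shrinks
monotonically as the object recedes (the ambient term becomes negligible
relative to the growing intrinsic term).

## Binocular geometry

The gaze construction is planar (horizontal slice): rotation centres at
`(±d/2, 0)` (defaults `d = 60 mm`, nodal offset `r_E = 7 mm`, optic/visual
angle `α ≈ 5°` available), straight ahead along +y, all angles
counterclockwise-positive. Eye angles are interpreted as optic-axis
rotations with `α` applied nasally on top; a switch accepts visual-axis
angles directly, since the source construction is ambiguous on this point.
The fixation point is the intersection of the two visual axes (explicit
"no fixation" error for parallel or diverging axes). The horopter applies
matched angular offsets to both visual axes and intersects corresponding
rays; with `α = 0`, `r_E = 0` it is, by the inscribed-angle theorem, the
circle through the fixation point and the two nodal points, and it
flattens as fixation distance grows. Retinal image size uses the reduced
eye: 17.2 mm per radian of subtended angle.

## Psychophysical task simulators

All deviations are signed counterclockwise-positive viewed from above; the
source material reports patterns rather than signed conventions, so the
convention is fixed here and mirror-antisymmetry is tested instead of any
absolute sign. Flat-plane geometry makes two predictions exact and worth
knowing when reading simulation output:

* equal-radius exocentric pointing: the connecting geodesic is the circular
  arc, so the pointer is aimed exactly half the separation angle outside
  the veridical chord (the veridical direction lies between the aimed
  direction and the egocentre, and rotates further egocentre-ward as the
  target recedes along the arc);
* equal-radius parallelity: in-plane parallel transport rotates every
  vector by the angular advance, so the deviation equals the separation
  angle, independent of rod orientation.

The gaze-averaging strategy takes the unit initial tangent at the pointer
and the unit terminal tangent at the target (the negated
target-to-pointer estimate, negated again by the strategy), compared in the
shared Cartesian chart, and averages once with equal weights; the averaged
direction is closer to veridical everywhere on the tested grids, exactly
veridical for symmetric tasks, and retains a separation-by-distance-ratio
interaction. Iterating the same two estimates does not change the mean, so
the iteration count is exposed only for strategy exploration. Collinearity
is the same computation with the rod-alignment reading. Out-of-plane loops
(e.g. geodesic quadrilaterals on a visual sphere) pick up genuine holonomy
equal to the enclosed spherical area, which the tests verify against the
polygon's angular excess; in-plane loops have none, consistent with the
flatness discussed above.

## The place-indexed memory and its synthetic scenes

The G-memory quantises cyclopean coordinates to 1° angular bins and
logarithmic radial bins of width `Δln r = 0.05` — uniform *perceived*
resolution, matching the logarithmic depth map. The overwrite rule stores
an incoming left/right feature pair only where the site is empty or the
stored pair's left–right difference norm is strictly larger (the incoming
pair was seen nearer the fovea); ties keep the existing entry for
stability, as the rule specifies strict inequality only.

The synthetic scene generator emulates exactly what the morphism algebra
needs and no more: opaque convex primitives (spheres, axis-aligned boxes),
surface points sampled uniformly, visibility by ray casting, and a
30-component feature vector per surface point that scales deterministically
as `1/r` with viewing distance. That scaling makes the default feature
morphism `H₂(r_i, r_j) = (r_i/r_j) I` exact, so `(++)` transport
self-consistency and fill accuracy are well defined (observed relative
errors are at round-off). The true form of `H₂` is unknown — the model
treats it as adaptively learned — so the scalar family is an explicit,
pluggable default, and any radial-pair-indexed linear map can be
substituted. What passing these tests shows is that the bookkeeping
(translation morphism `H₁`, feature morphism `H₂`, occlusion classes,
coverage monotonicity) is correct; it says nothing about real image
features, binocular noise, semi-transparency or reflections (twisted
bundles), none of which are modelled. Quantisation-bin collisions (two
surface points in one cell) are a real resolution limit of the model and
are treated as such in the tests rather than hidden by finer grids.

## Problem sizes

The shipped test-suite and acceptance runs use: geodesic families of 12–36
trajectories over 2–32 s; 100–500-draw property sweeps for metric and
spray identities; 6 random surface patches for the Gauss relation; toy
scenes of two primitives × 80 surface points over 2–6 places; and a single
geodesic triangle (three boundary-value solves) for the headline angle-sum
computation. These sizes were chosen so each property is exercised well
past its tolerance while a full run stays in the tens of seconds.

## Known limitations

* The roll angle about the gaze direction (the third cyclopean angle) is
  not modelled; rotational isometry of the metric is the only statement
  made about it.
* The spherical chart excludes the poles; configurations near them must be
  rotated first.
* No fits to experimental deviation magnitudes are attempted: published
  task data are not shipped with the model, so the psychophysical surface
  is validated by sign, monotonicity, antisymmetry and dominance patterns
  only.
* Binocular geometry is horizontal-plane only, and disparity is never
  estimated from image content; image-point vectors are opaque synthetic
  features.
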