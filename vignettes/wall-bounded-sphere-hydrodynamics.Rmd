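---
title: "Hydrodynamics of microspheres near channel walls: model, numerics, and the video pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamics of microspheres near channel walls}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wallstokes` estimates the hydrodynamic load on a micron-scale sphere near
the lower wall of a parallel-plate microchannel — the configuration of cell
rolling adhesion assays — and the translational and angular velocities the
sphere adopts when it is free.  This vignette explains the model and its
assumptions, the numerical scheme and its parameters, the synthetic-video
measurement module, and the design decisions behind each, together with the
package's known limitations.

## Physical model and assumptions

The fluid is Newtonian and incompressible, with dynamic viscosity `mu`
(0.0009–0.001 Pa s for aqueous buffers) and density `rho` (1000 kg m^-3).
At the scales of interest (sphere diameter `d` about 10 um, wall shear
rates 1–600 s^-1) the particle shear Reynolds number
`Re = shear_rate * d^2 / nu` is between 1e-4 and 2e-2, so the steady Stokes
equations are the default model; the convective term is retained as a
first-order correction (below), not in the operator.  The sphere is rigid,
neutrally buoyant (gravity neglected), laterally centred, and constrained to
the two degrees of freedom that matter in this geometry: translation `u`
along the flow and rotation `omega` about the spanwise axis.  Wall-normal
migration is frozen.  Reported `Tz` and `omega` are positive in the
forward-rolling sense.

Two ambient profiles are supported, both with the same wall shear stress
`WSS = mu dVx/dY` at the lower wall:

* linear, `Vx = (WSS/mu)(Y + H)` — the unbounded constant-shear ambient of
  the classical wall-correction model;
* parabolic, `Vx = -WSS (Y^2 - H^2)/(2 mu H)` — fully developed plane
  Poiseuille flow in a channel of height `2H` (100 um by default).

In wall-local coordinates (`y` measured from the wall) both are
`u_x(y) = c_s y + c_q y^2` with `c_s = shear_rate` and `c_q = 0` or
`-shear_rate/(2H)`.  Because Stokes flow is linear, every solve in the
package is assembled from four unit solutions per geometry — unit ambient
shear, unit ambient curvature, unit translation, unit rotation — sharing a
single matrix factorization; all WSS sweeps and both profiles follow
exactly by superposition.

## Boundary-element solver

The disturbance flow is represented by a single-layer potential on the
sphere surface with the image-system Green's function for a point force
near a plane no-slip wall, so the wall condition holds exactly and momentum
and continuity are satisfied identically by construction; the only
discretization is of the sphere surface and the only solve is a dense linear
system for the surface force density.  Force and torque equal (minus) the
integrals of the density: the ambient stress is self-equilibrated over the
sphere, and the density differs from the true disturbance traction only by a
constant multiple of the outward normal, which carries no load.  The
pointwise traction split reported by `surface_tractions()` pins that
constant by giving the disturbance pressure zero mean over the sphere; on a
rigid no-slip sphere the viscous normal stress vanishes, so the normal
traction is the pressure and the tangential part is the viscous vector.

**Mesh.**  The sphere is tiled by latitude bands subdivided in azimuth.
Band edges follow `theta_k = sqrt(2 eps) * sinh(c k / nb)` with
`eps = h/a` and `c = asinh(pi / sqrt(2 eps))`: the band height is then
proportional to the local gap scale `sqrt(eps + theta^2/2)`, the natural
length of the lubrication fields, and the spacing relaxes to near-uniform
when the sphere is far from the wall.  Azimuthal counts target unit aspect
ratio but are capped (24–40 per band by preset): the surface densities of
all flows treated here are low-order Fourier modes in azimuth, so azimuthal
refinement beyond a few dozen panels changes the results at the 0.1% level
only (checked numerically by doubling the cap).  Facet areas are exact
spherical-quad areas and centroids sit at the facet area centroid, which
makes the discrete closed-surface identities (`sum n ds = 0`,
`sum ds = pi d^2`) hold to rounding error — the same identities that make a
uniform pressure exert exactly zero discrete force and the pressure exert
exactly zero discrete torque.

**Quadrature.**  Off-diagonal entries are integrated adaptively: a
(sub)facet is evaluated by its centroid once its diameter is below
`1/near_fac` of the distance to the evaluation point or to its wall image
(the image of the contact facet lies only `2h` below it), otherwise it is
split 2x2, uniformly in `cos(theta)` and azimuth so sub-areas stay exact,
down to a capped recursion depth.  The direct self-term is
consistency-calibrated: the diagonal block is chosen so that the discrete
operator reproduces the exact uniform-density solution of a translating
sphere, making the unbounded Stokes drag exact at any resolution and
removing the leading self-integration error elsewhere.

**Resolution presets.**  `coarse` (40 bands, ~900 facets), `medium` (70,
~2100) and `fine` (110, ~4200) also scale the quadrature (`near_fac` 6/8/14,
depth 7/8/10).  At the hardest benchmark geometry (`h/a = 0.0138`) the
stationary force changes by 0.03% and the torque by 0.3% from medium to
fine, while the free-motion rotation rate — controlled by the
logarithmically singular lubrication resistances — changes by about 2%;
fine agrees with quadrature-saturated reference runs to 0.3%.  The mobility
problem is the quantity that drives the fine preset.  A single fine
factorization takes on the order of a minute on one CPU; medium takes
seconds, which is why the test suite runs at medium and below.

**Reduced domain.**  Truncating the channel to an 80 x 40 um sub-domain
with impenetrable free-slip far boundaries is emulated by one mirror
reflection of the wall kernel across the plane `y = 40 um` (the default
`confinement = "upper_freeslip"`); the reflection preserves the exact
no-slip wall and approximately cancels the normal velocity at the
truncation height.  The companion geometric object, `reduced_domain()`,
constructs the bulged duct whose outline area minus the sphere
cross-section equals the inlet area at every station: the bulge amplitude is
solved from that constraint exactly under the sphere and blended to zero
with a C1 cubic Hermite taper over a 0.2 um window at the sphere's edges
(an exactly area-preserving outline cannot be C1 at the sphere's edge, and
the taper keeps the area deviation under 1e-3 of the inlet area, the
documented tolerance).  In the boundary-integral setting the open exterior
plays the same blockage-free role as the bulge.  The side boundaries
(+-40 um) are not imaged; `domain_truncation_sensitivity()` doubles the
truncation height and removes it entirely, and the resulting force/torque
changes (a few tenths of a percent at the benchmark geometry, below the 1%
domain-doubling criterion) bound the truncation effect.  Domain length
defaults to eight sphere diameters with the sphere at mid-length; the
solver's results do not depend on it (the kernel is open in x), it sizes
the exported geometry and the control boxes.

**Free motion.**  With the resistance matrix `R` (negative-definite
diagonals, couplings equal by the Lorentz reciprocal theorem — the
measured asymmetry, under 1%, is a discretization diagnostic) and the
ambient loading `(F0, T0)` on the held sphere, the force-free/torque-free
state is `(u, omega) = -R^{-1}(F0, T0)`, followed by a superposed residual
evaluation.  `quasi_static_iterate()` reproduces the time-stepping
alternative — damped velocity updates proportional to the force and torque
imbalance, with step halving on divergence — and converges to the same
state within a few tens of steps from rest at the default damping 0.7 and
0.5% residual tolerance; it exists because it also accommodates the
convective correction, which breaks superposition.

**Convective term.**  The first-order effect of `rho (u . grad) u` on the
load is evaluated by the reciprocal theorem as a volume quadrature of the
convective integrand weighted by the unit-translation and unit-rotation
auxiliary fields.  For this fore-aft antisymmetric configuration the
correction to `Fx` and `Tz` largely cancels and the computed relative
corrections at WSS = 5 dynes cm^-2 are far below the 2% envelope asserted
in the tests — quantifying, rather than assuming, that the Stokes default
is safe in the assay regime (the leading inertial effect in this geometry
is wall-normal lift, which is outside the package's two degrees of
freedom).

## Wall-correction reference

`goldman_stationary()` / `goldman_free_motion()` evaluate the classical
constant-shear wall model: the sphere near a single plane wall in unbounded
linear shear.  The dimensionless conventions are
`Fx = 6 pi mu a (a+h) shear_rate F*`, `Tz = 4 pi mu a^3 shear_rate T*`,
`u = shear_rate (a+h) u_ratio`, `omega = shear_rate w_ratio`.  The factors
are computed by the package's own solver in linear mode on the open
half-space (no truncation plane) — the linear-mode solver and the classical
model describe the identical boundary-value problem — and can be cached to
a plain-text table (`goldman_factor_table()`) or supplied externally and
interpolated in `log(h/a)`.  Sanity anchors: as `h/a` grows the factors
approach 1 (and `w_ratio` approaches 1/2); toward contact `F*` and `T*`
plateau near 1.70 and 0.944 while the mobilities decay logarithmically.
The package does not re-derive the classical bipolar-coordinate series.

## Why the parabolic profile lowers both load and rotation

At `d/2H = 0.1` the parabolic ambient equals the linear one at the wall and
falls below it quadratically with height; over the sphere's extent the
deficit reaches 10% at the top.  The stationary force and torque are linear
functionals of the ambient profile, so the parabolic values are the linear
ones minus a curvature term — about 6% of the force and 12% of the torque
at the benchmark geometry (the curvature functional is validated against
the exact unbounded quadratic-flow force, where the discretization error is
at the 1e-3 level).  For the free sphere the same linearity acts twice:
`(u, omega) = -R^{-1}(F0, T0)` with a profile-independent resistance
matrix, so scaling the ambient loading down scales both velocities down by
nearly the same factor.  Two hard bounds follow for any wall-bounded Stokes
mobility: the free rotation rate cannot exceed half the local ambient
shear rate, and near contact it is further suppressed by lubrication
(`w_ratio` about 0.29 at `h/a = 0.0138`).  A freely rolling sphere at a
36 nm gap therefore cannot rotate at ~0.45 of the wall shear rate under
this model; reports of such rates from under-resolved moving-mesh
simulations or from particles travelling at larger gaps than nominal should
be interpreted with the lubrication resistance in mind.  The package
reports what the converged Stokes mobility gives.

## Synthetic Janus-particle videos

The generator emulates the fluorescence movies used to measure particle
kinematics: 25 frames/s, a 960 x 500 sensor binned 2 x 2 (stored frames
480 x 250), and a default object-plane pitch of 1.3 um per binned pixel —
the pitch is a configurable calibration, not a derived quantity.  Particles
are rendered in orthographic projection along the camera axis: the
polystyrene core is uniformly fluorescent and a metal-coated cap of
half-angle 45 degrees (default) blocks emission; the cap pole rotates in
the flow/wall-normal plane as the particle rolls, so the projected bright
area oscillates exactly once per revolution, between the full disc and a
bright annulus whose equivalent diameter (5.7 um) stays above the 5 um
detection gate — the choice that keeps synthetic particles continuously
trackable, as real tracks are.  Rendering uses 2 x 2 subpixel
anti-aliasing plus white Gaussian noise (sd 0.02 of the intensity scale);
rotation rates at or above the Nyquist bound `pi * frame_rate` are refused.

The measurement pipeline mirrors assay practice: threshold (default 25% of
the foreground-background contrast above background), connected-component
labelling (EBImage), a size gate on twice the radius of the minimum
enclosing circle (Ritter's algorithm; particles at or below 5 um are
discarded), and frame-to-frame association restricted to forward
displacement below half the previously detected diameter per elapsed frame
within a 15-degree divergence angle of the flow direction, with a
configurable look-ahead window for short dropouts and a sub-pixel exemption
for the phase wobble of the bright-lune centroid.  Mean velocity comes from
the total tracked distance over the track duration; angular velocity from
the cycle count of the projected-area series, counted as upward midline
crossings with a hysteresis band (robust to the flat extremes of the area
signal) at sub-frame interpolated times, cross-checked against the
zero-padded FFT's dominant frequency and flagged on disagreement.
Constant-area tracks (plain spheres) are flagged `no_estimate` via a
relative-standard-deviation gate (0.05) that separates rotation signals
(relative sd above 0.1) from pixelation jitter (below 0.04).

What passing the video tests shows — and does not.  Across ten seeds at
assay-scale kinematics the pipeline recovers the generator's truth within
2% (translation) and 5% (rotation).  The generator does not model
photobleaching, depth-of-field asymmetry, motion blur (the exposure setting
is metadata only), out-of-focus halos, or particle-particle occlusion, so
these figures certify the estimator logic, not robustness to every
real-microscopy artefact.

## Numerical choices and degenerate inputs

* Direct LAPACK solve of the dense system; deterministic given the mesh (no
  randomization anywhere in the solver), with a sampled linear-system
  residual stored in the solution metadata (machine level).
* `gap <= 0` is refused (contact singularity); gaps thinner than the finest
  resolvable facet layer at the chosen preset are refused with guidance to
  raise the resolution (at least three bands must land in the gap zone).
* A problem without a sphere returns the analytic ambient profile; zero WSS
  returns an identically zero field.
* Mass conservation is checked, not assumed: net flux through a closed
  control box around the sphere (Gauss-Legendre faces; the wall face is
  identically zero) stays below 1e-6 of the influx, the boundary data give
  exactly zero flux through the sphere, and a probe-based central-difference
  divergence is reported.
* Units are SI internally; reports use dynes cm^-2, pN, pN um, um s^-1 and
  rad s^-1, with 1 dyn cm^-2 = 0.1 Pa.  Viscosity defaults are per-case
  (0.0009 Pa s for the microsphere benchmarks, 0.001 Pa s for the 12 um
  lymphocyte case), never global.

## Problem sizes used by the shipped checks

The test suite runs at coarse/medium resolution (up to ~2100 facets, a few
seconds per factorization) plus one fine solve for the reference values;
`scripts/acceptance.R` runs the benchmark cases at fine resolution (~4200
facets, two factorizations, everything else by superposition) in a few
minutes on one CPU.  These sizes were chosen from the convergence study
above: medium is inside the 1% band for every reported quantity and fine
inside ~0.3%.

## Known limitations

* One sphere only; no particle-particle interactions.
* Two kinematic degrees of freedom; no wall-normal lift or migration, no
  sedimentation, no transient (added-mass/history) effects.
* Rigid spheres; cells deform, and deformation changes both load and
  mobility.
* The free-slip truncation boundary is a single-reflection approximation
  (quantified by the sensitivity check, not exact); side boundaries are
  left open.
* The inertial correction is first order and evaluated on a modest
  quadrature — adequate for bounding a sub-percent effect, not for finite
  Reynolds number studies.
* The video generator idealizes the optics (see above).
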