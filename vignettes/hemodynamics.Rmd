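---
title: "Aneurysm hemodynamics with hemoflow: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aneurysm hemodynamics with hemoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemoflow)
```

hemoflow reimplements a complete rupture-point hemodynamics analysis for
saccular intracranial aneurysms: idealized aneurysm geometry, vascular
surface-mesh processing, pulsatile incompressible flow, the wall shear
stress (WSS) index panel, rupture-site region statistics, and the
computational half of a particle image velocimetry (PIV) comparison.
Patient CT segmentations are not available to this package, so every stage
is exercised on parametric idealized geometries whose morphology spans the
same ranges as the clinical series the analysis was designed around
(dome size about 9-13 mm, parent artery radius about 1.6-2.2 mm, neck
diameter about 5-8 mm, aspect ratio about 1.1-1.6). This vignette
documents the models, the defaults and why they were chosen, and what the
synthetic test bed does and does not demonstrate about patient data.

## Synthetic geometry

`build_idealized_aneurysm()` describes the lumen implicitly as the union of
a circular parent tube and a spherical dome (optionally a secondary bleb
sphere, or a Y-bifurcation layout with two daughter branches). The neck is
parametrized by its radius: the neck plane is placed where the dome
sphere's cross-section equals the requested neck radius, and by default the
sphere centre height is chosen so this plane sits just inside the parent
wall, giving an open neck without a deep sphere-tube overlap.

Meshing clips a Freudenthal tetrahedral lattice (six tetrahedra per cube)
against the implicit surface. Lattice vertices within 0.3 spacings of the
zero level set are first projected onto it (isosurface stuffing), which
bounds the quality of the cut cells; remaining crossing edges are resolved
by bisection, and cut prisms are split into tetrahedra with the
global-vertex-order diagonal rule so neighbouring cells stay conforming.
The returned surface is the boundary of this conforming volume mesh and is
therefore watertight and outward-oriented by construction. The parent
vessel axis is aligned with a lattice direction, so the inlet and outlet
sections of the sidewall layout coincide with lattice planes and are
exactly planar circles perpendicular to the axis. The angled daughter-branch
caps of the bifurcation layout are instead resolved by the implicit surface
and carry a rim chamfer of the order of the edge length; flow verification
cases therefore use the sidewall layout or the structured tube.

Two deliberate conventions:

* all mesh coordinates and file formats are in millimetres; the solver
  converts to SI internally, and all stresses are reported in Pa;
* the random seed affects only bleb-placement jitter and fixture noise;
  the geometry is otherwise deterministic, so identical configurations
  mesh identically.

`build_straight_tube()` and `tube_volume_mesh()` provide the verification
geometry: a spiderweb-triangulated disc extruded along the axis. Cross
sections are exactly circular and the caps exactly planar, and the axial
spacing may be chosen coarser than the in-plane edge length, which costs
nothing for axially invariant (Poiseuille) flow and keeps the linear
systems small.

## Surface processing and morphometry

`smooth_surface()` implements the two standard umbrella-weight filters:
Taubin lambda|mu smoothing (`lowpass`, defaults lambda = 0.5,
mu = -0.53), which suppresses mesh noise while bounding volume shrinkage,
and plain Laplacian relaxation (`laplace`, default step 0.5), which
shrinks monotonically. `extend_openings()` extrudes each tagged opening
along its mean cap normal until the straight run between the opening and
the dome is at least six opening diameters, the usual criterion for
letting a prescribed inlet profile develop before it reaches the sac; the
cap itself is translated rigidly, so the opening radius is preserved
exactly and the terminal section stays perpendicular to the extension
axis.

`compute_morphometry()` reports size (maximum pairwise distance between
dome vertices, computed exactly), dome area, dome volume (the dome surface
closed by a fan over its boundary loop), and, when a neck plane is
recorded, neck diameter, height and aspect ratio. The neck diameter is the
maximum chord of the intersection polyline between the neck plane and the
dome-side surface; when the dome boundary already lies in the plane (an
ideal hemisphere) the boundary loop itself is used. Imported meshes
without a defined neck return the partial report, mirroring clinical cases
where the neck cannot be outlined.

## Flow model

The solver treats blood as an incompressible Newtonian fluid (dynamic
viscosity 3.5 mPa s, density 1050 kg m^-3 by default) in a rigid lumen,
governed by the Navier-Stokes equations. Boundary conditions are no-slip
on the wall and dome, a parabolic velocity profile on the circular inlet
with spatially averaged magnitude prescribed in time, and zero
pseudo-traction (mu du/dn - p n = 0) on the outlets. The gradient form of
the viscous term is used deliberately: its natural outlet condition is
satisfied exactly by fully developed flow, so the verification tube does
not suffer outlet distortion. The discrete inlet profile is rescaled so
that its facet-quadrature flux equals the requested flux exactly, which
makes the imposed flux, not its interpolation, the controlled quantity.

The inflow waveform is pinned by three constraints - peak systolic
velocity (PSV), end diastolic velocity (EDV) and time-averaged velocity
(TAV); the defaults 0.45 / 0.2 / 0.3 m/s at 60 bpm are the study
conditions used throughout. Because only these three constraints are
known, the shape is the simplest smooth curve satisfying them exactly: a
raised-cosine systolic pulse on a diastolic plateau whose width is solved
in closed form from the mean constraint (flipping to a raised-cosine dip
when the mean lies above the PSV/EDV midpoint). The systolic peak is
placed at a quarter of the cycle, a typical early-systole timing; users
with measured waveforms can pass sampled curves instead. All three
constraints are re-verified numerically on construction.

### Discretization

Velocity and pressure are discretized with the MINI element: linear
elements for both fields with a cubic velocity bubble per tetrahedron.
The bubble is statically condensed against the Stokes operator, which
yields exactly an element-wise pressure-Laplacian stabilization with
coefficient `tau_e = (int b)^2 / (mu int |grad b|^2)`; the bubble's
convective and transient couplings are dropped, a standard quasi-static
bubble simplification. Convection is linearly implicit - the advecting
field is the previous Picard iterate (steady) or the BDF extrapolation of
the previous steps (transient) - with a Temam term for discrete stability.
Each step or sweep solves one sparse system with Eigen's SparseLU; the
symbolic factorization is reused. Because the systems are solved directly
and the stabilization matrix has zero row sums, the discrete continuity
equation tested with the constant pressure function gives exact global
mass balance: inlet and outlet fluxes cancel to rounding at every step,
independent of mesh resolution.

Time stepping is BDF (order 2 by default, order 1 for the first step)
with a default step of T/100 over two cycles, statistics taken from the
final cycle; the run starts from rest with the waveform ramped over the
first tenth of cycle one to avoid an impulsive start. One washout cycle
is the minimum defensible choice and is configurable; the kinetic-energy
trace is monitored and a blow-up aborts the solve. Steady solutions use
Picard iteration with adaptive under-relaxation (full steps while the
iteration contracts, backed off when it stalls).

### Wall shear stress

Wall traction is recovered by the consistent-flux method: the
unconstrained momentum residual at a wall node equals the weak boundary
term, so dividing by the lumped wall mass matrix gives a superconvergent
nodal traction; the per-facet WSS vector is its tangential projection,
flipped to the stress exerted by the fluid on the wall. On the Poiseuille
tube this recovers the closed-form wall shear within a few percent at a
0.2 mm section edge, where a naive per-element gradient is biased low by
the distance of the first cell centroid from the wall.

## Index panel

With `wss(x, t)` the WSS vector over one period T:

* `TAWSS = (1/T) int |wss| dt`, periodic trapezoid quadrature;
* `OSI = (1/2)(1 - |int wss dt| / int |wss| dt)`, defined as 0 where the
  denominator vanishes; always in [0, 0.5];
* `PWSS` = |wss| at the stored sample nearest the waveform's systolic
  peak - the peak is defined by the inflow waveform, not by the local
  shear history;
* `LSA` = percentage of dome area with |wss| below 10 percent of the
  spatially averaged WSS; the averaging region is not fixed by the
  definition alone, and hemoflow follows the convention of referencing
  the parent-artery wall mean (configurable to the dome mean). `PLSA`
  evaluates at the systolic peak; `TALSA` integrates the instantaneous
  low-shear area over the cycle, using the instantaneous threshold (a
  cycle-mean threshold variant can be obtained by passing a fixed
  reference, but the instantaneous rule is the default);
* `NTAWSS`, `NPWSS` = dome averages of TAWSS / PWSS as percentages of the
  parent-artery averages.

All regional statistics are area-weighted facet averages, which are stable
under refinement and consistent with the integral definitions; maxima are
facet maxima. The synthetic wall-field generator (`synth_wall_field()`)
builds shear histories with constant per-facet magnitudes and uniform time
samples, for which every index above has an exact closed form; the index
kernels are required to match those ground truths to 1e-10 relative,
which verifies the quadrature and bookkeeping exactly, independent of the
flow solver.

## Rupture site

The rupture point is an input (clinically it is marked on imaging after
surgery). The site region is the set of wall facets whose centroid lies
within a sphere of default radius 0.5 mm around the marked point, snapped
to the nearest wall vertex first (the snap distance is reported).
Centroid inclusion rather than exact sphere-triangle clipping is used
because it is simple and converges under refinement. Site-versus-dome
comparisons report area-weighted averages and the relative percentage
difference `100 (site - dome) / dome` to one decimal. The qualitative
regimes are made explicit by thresholds: a site counts as
`low_wss_high_osi` (vortex type) when TAWSS is depressed and OSI elevated
by more than 25 percent each, as `high_wss_jet` when the pattern is
reversed; both thresholds are configurable, since the underlying clinical
classification is qualitative.

## PIV comparison (computational side)

`trace_pathlines()` integrates massless particles through the steady
velocity field with adaptive Dormand-Prince RK45 (relative tolerance
1e-10), over the 10 ms camera exposure; traces leaving the lumen are
truncated at the wall. Focal-depth banding keeps traces whose midpoint
lies within half the depth of field (DOF) of the measurement plane and
attaches a greyscale depth code. The default DOF is 248 micrometres, the
measured value of the reference optical setup; figure captions of the same
setup quote 247 micrometres, and the parameter is configurable precisely
because the two printed values disagree. `sample_velocity_line()`
evaluates the velocity magnitude along a probe segment and its two copies
shifted by plus/minus the DOF. Kinematic similarity between blood and a
circulating medium is checked through their density-to-viscosity ratios
(equal Reynolds number at fixed geometry and flux); finite particle size
and density are out of scope - the computational traces are massless by
design.

## Problem sizes and numerical tolerances

The package's own verification suite runs entirely on a single CPU core;
the problem sizes are chosen as the coarsest ones at which each property
is demonstrated cleanly:

* Poiseuille verification: tube R = 2 mm, L = 24 mm, section edge 0.2 mm,
  axial spacing 1.5 mm (axially invariant flow), about 23k unknowns;
  wall WSS and centreline velocity agree with the closed form within 5
  percent.
* Mesh dependency: the default sidewall aneurysm at 169 mL/min steady
  flow, re-meshed at h = 0.78, 0.68, 0.58 mm; the dome-averaged velocity
  of the two finest meshes agrees within 2 percent.
* Pulsatile conservation: the default aneurysm at h = 1.0 mm, T/100 steps,
  two cycles; the inlet/outlet flux balance holds to rounding (far below
  the 1e-3 acceptance level) because it is a structural property of the
  discretization.
* Index kernels: fixture ground truths to 1e-10; pathline oracles to 1e-6
  against closed-form advection.

Steady Picard iterations stop at a relative change of 1e-5; mass balance
does not depend on this tolerance (continuity is enforced exactly every
sweep), only the convective consistency does.

## What the synthetic test bed does not show

The generator produces smooth idealized lumens: no surface roughness,
no tortuous parent vessels, no irregular multi-lobed sacs, and a neck
plane known by construction rather than outlined by an operator. Passing
the suite therefore demonstrates that the numerics (meshing, solver,
index kernels, region statistics) are correct and internally consistent,
not that patient-specific predictions are accurate: with real
segmentations the dominant error sources are segmentation quality,
boundary-condition uncertainty (inlet waveforms are population averages,
outlets are zero-traction rather than impedance models) and wall
compliance, none of which the synthetic fixtures emulate. Within those
modelling assumptions, the solver itself is verified against closed
forms, and mesh-dependency and temporal-refinement checks bound the
discretization error of the reported dome averages.

## Known limitations

* Rigid walls, Newtonian rheology, zero-traction outlets - no
  fluid-structure interaction, shear-thinning or Windkessel models.
* The lattice mesher produces some poorly shaped (but positive-volume)
  cut cells; the stuffing threshold of 0.3 spacings bounds the effect,
  and all reported statistics are integral quantities.
* Steady solves at the coarse default resolutions under-resolve the slow
  dome recirculation; dome-averaged quantities converge, but pointwise
  fields at those resolutions are qualitative.
* Direct sparse factorization bounds the practical mesh size at roughly
  1e5 unknowns per solve on one core.
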