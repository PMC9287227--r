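---
title: "Modelling applanation tonometry with tonofem: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling applanation tonometry with tonofem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tonofem` simulates the mechanics of applanation tonometry: a rigid
flat-ended cylindrical probe is pressed a prescribed plunging depth into
the cornea of a pressurized cornea–sclera shell, and the axial reaction
force on the probe — the applanation force — is computed together with the
deformation and stress fields. This vignette documents the model, its
parameters, the numerical machinery, and the design decisions taken where
the problem statement left the construction open. It states no result that
the package's test suite or `scripts/acceptance.R` does not itself compute.

## The mechanical model

**Geometry.** The eye is a closed thin shell of revolution-like form with
quadrant asymmetry, built per meridian quadrant (superior, inferior,
nasal, temporal) and lofted azimuthally:

* the anterior cornea is a circular arc of radius 7.75 mm (apex at the
  origin, +X toward the posterior pole);
* the corneal wall thickness blends linearly in arc length from 0.52 mm at
  the apex to 0.67 mm at the limbus;
* at the limbus the outer surface kinks by (180° − A) where A is the
  quadrant's corneoscleral junction angle (178.1/177.7/173.9/177.0° for
  S/I/N/T);
* the sclera continues as an ellipse arc whose vertex lies on the axis at
  the posterior pole (axial length 22.7 mm), tangent-matched to the
  post-kink direction; the scleral wall is 0.317 mm thick, optionally
  augmented by the 0.298 mm choroid (scleral material, off by default);
* a junction band of 1.5 mm arc length straddles the kink; it is tagged as
  its own region per quadrant and the wall thickness blends smoothly
  (smoothstep) from 0.67 to 0.317 mm across it.

Two constructions were considered for closing the sclera, because the
printed dimensions over-determine the meridian. With both the corneal arc
(7.75 mm) and a scleral circle (11.2 mm) centred on the axis and the
posterior pole fixed by the axial length, the junction angle is forced to
≈171°, outside the printed 173.9–178.1° range, and the limbus lands at a
radius of 3.6 mm — a 7 mm corneal diameter, far below anatomy. The package
therefore fixes the corneal base semi-diameter at 5.85 mm (the
white-to-white corneal semi-diameter; `corneal_base_radius`, exposed as a
parameter) and solves the unique axis-vertex ellipse through the limbus
with the required tangent. The resulting scleral semi-axes are ≈11.5–11.75
mm axially (validated to lie within 20% of the nominal 11.2 mm scleral
radius — the geometric-infeasibility error otherwise) and ≈8.2–8.6 mm
equatorially: the printed near-tangent junction angles force a slimmer
globe on any convex closure. Junction angles, corneal curvature and
thicknesses, and the axial length are honoured exactly; the ellipse
closure also makes the 180°-angle limiting case an exactly tangent,
inflection-free meridian.

The loft interpolates the four profiles with 4-point trigonometric
(periodic) interpolation in azimuth: exact at the key azimuths, smooth in
between, and exactly axisymmetric when the four profiles agree.

**Materials.** Homogeneous, isotropic, linearly elastic tissues: cornea
E = 0.2 MPa, ν = 0.43; sclera E = 2 MPa, ν = 0.4. The junction band
defaults to scleral material (only two tissue property sets are modelled;
the map is configurable). Densities are carried but unused — the analysis
is quasi-static. The probe is not meshed: its modulus is ~10⁶ times the
corneal modulus, so it is treated as an analytic rigid surface.

**Loads and constraints.** The IOP (clinically 10–20 mmHg; converted at
1 mmHg = 1.333224·10⁻⁴ MPa, so 20 mmHg = 2.66645 kPa) acts as a uniform
dead normal pressure on the closed inner surface, oriented outward from
the cavity. Rigid-body motion is removed by the "remote displacement zero"
condition: six averaged multiplier constraints (zero mean translation and
zero mean infinitesimal rotation of the outer scleral node set). The
alternative `posterior-patch` mode clamps all nodes beyond 140° polar
angle; the test suite checks the two modes give contact forces within 5%
(a Saint-Venant insensitivity check).

**Contact.** The probe face is advanced along +X in equal displacement
increments (default 10). Contact is frictionless and node-to-rigid-surface
with penalty regularization; candidates are the corneal outer-surface
nodes within the probe radius. Plunging depth is measured from first
contact with the *pressurized* eye, so zero depth gives exactly zero force
at any IOP. An optional rim fillet recedes the face near the probe edge;
the default tip is ideally flat and sharp-rimmed.

## Why the probe phase is linearized about the pressurized state

In plain linear kinematics a flattened membrane patch carries the pressure
behind it by bending, not by membrane rotation — so the Imbert–Fick
component of the applanation force (pressure × applanated area), the
dominant term at clinical depths, never reaches the probe. The package
therefore assembles the initial-stress (geometric) stiffness of the IOP
prestate and adds it to the material stiffness for the probe phase —
standard linear-perturbation ("stress-stiffening") practice. This is the
package's one deliberate departure from a plain small-strain default; the
flag `stress_stiffening = FALSE` restores the plain operator, and an
experimental `updated_geometry = TRUE` additionally re-assembles the
tangent on the inflated configuration. With the IOP at zero the default
and plain operators coincide, which is what the linear-scaling test
(halving E halves the force) relies on.

## Numerical machinery

* **Elements.** Trilinear hexahedra with 2×2×2 Gauss quadrature, augmented
  by nine Wilson/Taylor incompatible bending modes condensed at element
  level; the centroid-Jacobian correction keeps the patch test exact on
  distorted meshes (asserted to 10⁻¹² in the suite). The structured sweep
  collapses hexahedra to wedges at the two poles; collapsed elements fall
  back to the plain formulation (their interior quadrature Jacobians stay
  positive).
* **Meshing.** Structured azimuth × meridian × thickness sweep; the
  meridian parameter gives 45% of its range to the cornea with a power
  grading (exponent 1.5) that refines toward the apex so that several
  node rings lie under the probe face. Presets: `coarse` (24×16×2),
  `reference` (32×24×2, the reference resolution: its average in-plane element
  size of ≈1.0 mm is within a factor of two of the ~2 mm reference element
  size; node counts are not a contract — the reference mesh used quadratic
  elements), `fine` (48×40×3, used for mesh-dependence checks).
* **Linear solves.** Sparse symmetric assembly (Matrix package). For the
  multiplier-constrained system the package factorizes a slightly shifted
  stiffness (shift 10⁻⁶ of the mean diagonal) with supernodal Cholesky,
  solves the 6×6 constraint Schur complement, and removes the shift by
  iterative refinement to a 10⁻¹² relative residual — an exact saddle-point
  solve at Cholesky cost. Solutions are checked against a 10⁻⁹ residual.
* **Contact solves.** Because the operator is linear, each active-set
  iteration is performed exactly on the condensed flexibility of the
  candidate contact degrees of freedom (Woodbury identity): one
  factorization and one flexibility matrix per probe, then each increment
  costs a dense solve of the active set. The penalty per node defaults to
  `1e3 · E_cornea · tributary_area / corneal_thickness`; if the residual
  penetration exceeds the 10⁻⁴ mm gap tolerance the solve restarts with a
  10× stiffer penalty (the reaction force is penalty-insensitive to <1%,
  which the suite asserts). Active-set updates drop nodes with negative
  pressure and add penetrating nodes; non-stabilization within 100
  iterations is an error reporting the last active-set size and
  penetration.
* **Stress recovery.** Quadrature-point stresses are volume-averaged per
  element; von Mises from the deviatoric invariant; total deformation is
  the nodal displacement norm. Reported stress maxima are therefore
  mesh-regularized element averages — deliberately so, since the flat
  punch's rim stress is singular in the continuum limit.
* **Verification oracles.** The pressurized sphere (scleral dimensions,
  20 mmHg) is solved at 16×16×2, 24×24×2 and 48×48×3; the FE hoop stress
  is measured by through-thickness linear extrapolation of the layer-mean
  tangential stress to the inner surface (surface stress recovery), and
  gated at 2% against pR/(2t) at the finest resolution. The exact Lamé
  inner-surface stress is itself ≈1.5% below pR/(2t) at this thinness
  ratio, so a volume-average could never meet the gate; the convergence
  test tracks the error against the Lamé value. The Boussinesq flat-punch
  fixture (20×20×20 mm block, graded toward the punch, E = 0.2 MPa,
  ν = 0.43, a = 0.85 mm, δ = 0.1 mm) is gated at 5% against
  F = 2aEδ/(1−ν²).

## What the generator emulates — and what it does not

The geometry module is the pipeline's synthetic-data generator: its
defaults *are* the study conditions (the printed ocular dimensions, tissue
constants, probe diameters, depth and IOP grids). What passing tests show
is that the discrete model reproduces closed-form continuum mechanics and
the study's own force scales under those conditions. They do not show
fidelity to living eyes: real corneas are viscoelastic, fibre-reinforced
and nonlinear; the tear film, aqueous-humor dynamics, orbital fat and
extraocular muscles are absent; the globe closure implied by the printed
junction angles is slimmer than anatomy; and reference simulation values
from commercial solvers depend on their unpublished meshes, element types
and stress reporting (nodal extremes at the singular probe rim can far
exceed any element-averaged value). The known residual gaps are: the
Goldmann-probe force series, whose printed values lie below the printed
1.7 mm series at equal depth (impossible under contact-area monotonicity,
which our model obeys and the suite asserts); the ~0.2 MPa reference
stress maximum (a rim-singular nodal value); and deformation maxima quoted
relative to a nearly uninflated reference state, reachable only with a
fully nonlinear prestate. Probe-size near-independence holds in this model
at shallow depth (0.3 mm) and degrades as the larger probe engages the
limbus.

## Problem sizes and runtime

The default test-and-acceptance problem sizes are chosen so the whole
suite runs in minutes on one CPU: the reference preset has ≈2.2k nodes
(6.6k DOF, 1.5k elements), the fine preset ≈29k DOF, the punch block
≈33k DOF. Forces at the reference and fine presets agree to ≈1–3%, which is
why it is the resolution for all reported
numbers.

## Limitations

Linear kinematics with a single prestress linearization (no large-strain
membrane stiffening, no follower-pressure tangent); two homogeneous
isotropic tissues; frictionless contact without a tear film; quasi-static
loading only; structured sweep meshes only (no unstructured or adaptive
refinement). These mirror the scope of the underlying study; the module
boundaries make each a natural extension point.
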