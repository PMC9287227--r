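# tonofem

Finite-element simulation of corneal applanation tonometry in R.

Tonometers estimate intraocular pressure (IOP) by pressing a probe against
the cornea and measuring the reaction ("applanation") force. How that force
depends on the plunging depth of the probe and on the IOP itself matters for
instrument design: too much force risks damaging the eye, and the
force-depth relation is the feedback signal a tonometer ultimately inverts.
`tonofem` models this measurement end to end:

* a **parametric asymmetric cornea–sclera shell** built from published
  ocular dimensions — corneal anterior radius 7.75 mm, central/peripheral
  corneal thickness 0.52/0.67 mm, scleral thickness 0.317 mm, axial length
  22.7 mm, and four quadrant-specific corneoscleral junction angles
  (superior 178.1°, inferior 177.7°, nasal 173.9°, temporal 177.0°), lofted
  azimuthally between the four meridian profiles;
* a **structured hexahedral mesh** with the 9-region partition (1 cornea,
  4 sclera and 4 junction quadrants) and named surface sets for pressure,
  contact and constraint;
* **small-strain isotropic linear elasticity** (cornea E = 0.2 MPa,
  ν = 0.43; sclera E = 2 MPa, ν = 0.4), consistent internal pressure
  loading (1 mmHg = 1.333224·10⁻⁴ MPa), and "remote displacement zero"
  rigid-body removal;
* **frictionless rigid-punch contact**: a flat-ended cylindrical probe
  (1.7 mm standard, 3.06 mm Goldmann, 2.0 mm validation presets) advanced
  along the apex axis under displacement control, with penalty
  regularization and active-set iteration; the probe phase is linearized
  about the pressurized state (initial-stress stiffness), which carries the
  Imbert–Fick part (pressure × applanated area) of the reaction force;
* a **sweep pipeline** tabulating force F(depth, IOP), maximum total
  deformation and maximum von Mises stress over the study grid
  (depths 0.3–0.7 mm, IOP 10–20 mmHg), with linear force-relation fits
  (F = α + β·depth per IOP; dF/dIOP per 5 mmHg) and CSV/JSON/VTU output.

Every solver building block is gated by closed-form oracles: the
pressurized spherical shell (hoop stress pR/2t, Lamé solution) and the
Boussinesq rigid flat punch on an elastic half-space
(F = 2aEδ/(1−ν²)), plus patch tests, rigid-body nullity and work-balance
checks.

## Worked example

Build the default eye at the reference resolution and press the standard
1.7 mm probe 0.5 mm into the cornea at 20 mmHg:

```r
library(tonofem)

model <- build_eye_model(resolution = "reference")
model$mesh
#> <shell_mesh> type 'eye': 2214 nodes, 1536 elements, 9 region tag(s)
#>   resolution 32 x 24 x 2 (azimuth x meridian x thickness)

lc  <- load_case(iop = 20, probe = probe_spec(1.7), target_depth = 0.5)
res <- solve_indentation(model$mesh, model$materials, lc, model = model$cache)
res
#> <solve_result> depth 0.5 mm, IOP 20 mmHg, probe 1.7 mm
#>   reaction force 0.027999 N (64 active contact nodes, converged: TRUE)
#>   max total deformation 0.3295 mm; max von Mises 0.04824 MPa in 'sclera-nasal'
```

The probe carries ≈ 0.028 N at this grid point: the IOP pushing against the
flattened patch plus the elastic resistance of the corneal shell. The
deformation maximum (0.33 mm) sits on the pressurized cornea outside the
contact patch; the stress maximum sits in the thin nasal sclera/limbus
where the wall is thinnest and the junction kink is sharpest.

The full study grid and the fitted relations:

```r
cfg <- sweep_config()                     # 0.3-0.7 mm x 10/15/20 mmHg x 1.7 mm
tab <- run_sweep(cfg, model = model)
rel <- fit_force_relations(tab)
rel$iop_sensitivity$slope_n_per_5mmhg    # ~0.0032 N per 5 mmHg of IOP
write_outputs(tab, rel, outdir = "out")  # sweep.csv, relations.json, ...
```

A thin CLI wraps the same functions
(`exec/tonofem <build-mesh|solve|sweep|verify>`); `verify` runs the oracle
suite and exits nonzero if any gate fails.

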