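Package: tonofem
Title: Finite-Element Simulation of Corneal Applanation Tonometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric finite-element model of the human cornea-sclera shell
    under intraocular pressure, indented by a rigid flat-ended cylindrical
    tonometer probe. Builds an asymmetric lofted eye geometry from printed
    ocular dimensions, sweeps it into a tagged hexahedral mesh, assembles
    small-strain isotropic linear elasticity with consistent pressure loading
    and rigid-body ("remote displacement zero") constraints, and solves
    displacement-driven frictionless penalty contact to extract the
    applanation force as a function of plunging depth and intraocular
    pressure. Includes closed-form verification oracles (pressurized
    spherical shell, Boussinesq flat punch) and a sweep pipeline that
    tabulates force-depth-IOP relations, deformation and von Mises stress
    summaries, and exports fields as VTU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
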