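Package: conebend
Title: Hygromorphic Bilayer Bending of Pine Cone Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanical model of passive-hydraulic actuation in pine cone
    seed scales. The proximal bending zone is idealized as a tapered
    two-layer laminate (an actively swelling sclereid layer bonded to a
    stiff sclerenchyma fiber layer) whose humidity-driven eigenstrain
    mismatch generates curvature, computed per cross-section from composite
    beam theory and integrated to a finite-rotation opening angle. Includes
    humidity-dependent tissue modulus curves, inverse calibration of the
    passive-layer modulus and of the active-layer contraction against
    measured opening angles, drying sweeps along a coupled
    contraction-stiffening path, and a seeded synthetic-observation
    generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
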