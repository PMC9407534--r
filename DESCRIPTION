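Package: gelfrac
Title: Phase-Field Fracture of Thin Hydrogel Shell Structures
Version: 0.1.0
Authors@R:
    person("gelfrac", "developers", email = "gelfrac@example.org",
           role = c("aut", "cre"))
Description: Quasi-static phase-field fracture simulation for thin,
    possibly curved, hydrogel membranes and shells discretized by
    triangle meshes. Combines a constant-strain membrane finite element
    with a tension/compression split of a compressible neo-Hookean
    energy, an Ogden hyperelastic model for soft-tissue substrates, a
    vertex-based phase-field (damage) equation discretized with
    cotangent edge weights and barycentric vertex areas from discrete
    differential geometry, and a staggered displacement/damage driver.
    Ships parametric mesh generators for benchmark scenarios (notched
    plate, perforated spherical shell, fibered strip, curved cap with a
    bonded patch), OFF/OBJ readers, VTU/PVD time-series output and CSV
    force-displacement records, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
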