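Package: steermd
Title: Real-Time Steered Molecular Dynamics for Tip-Based Single-Molecule Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical molecular-dynamics engine for interactive manipulation of a
    single planar organic molecule by a metallic scanning-probe tip over an fcc(111)
    substrate. Provides molecular-graph construction with canonical enumeration of
    bond, angle and dihedral interaction tuples and closed-form per-atom force-count
    bounds; harmonic intramolecular terms, Lennard-Jones and Morse metal-molecule
    potentials with a configurable tip/substrate affinity table, and a second-moment
    (Gupta-style) many-body metal potential; a two-dimensional cell-list neighbor
    search with capped cell occupancy; a multiple-time-step velocity-Verlet
    integrator coupling the heavy-metal and light-molecule subsystems with a
    constant-friction thermostat; builders for fcc(111) slabs, pyramidal tips and
    molecule placement; scripted tip steering with a quasi-static rate guard; and
    extended-XYZ / JSON / CSV input-output plus verification and operation-count
    benchmark harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
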