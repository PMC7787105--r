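Package: cyclophase
Title: Hybrid Cryo-EM/X-Ray Phasing of Cyclic Oligomer Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for phasing crystals of cyclic (Cn) protein
    oligomers with the help of a partial atomic model built from a
    medium-resolution cryo-EM map. Detects cyclic non-crystallographic
    symmetry from X-ray amplitudes via the self-rotation function, expands a
    partial monomer into a Cn ring, places the ring in the crystal by a
    symmetry-constrained molecular-replacement search, diagnoses cryo-EM
    magnification (pixel-size) error from per-protomer rigid-body shifts, and
    recovers an interpretable map by density modification (solvent
    flattening, histogram matching, NCS averaging) with resolution-stepped
    phase extension. Includes a synthetic-fixture generator that builds fully
    known polyalanine ring "crystals" so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
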