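Package: interwater
Title: Water-Mediated Hydrogen-Bond Bridges at Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of water-mediated hydrogen bonds across protein-protein
    interfaces in molecular dynamics trajectories of ternary complexes formed
    by molecular glues. Provides geometric hydrogen-bond detection with
    distance/angle criteria, enumeration of water bridges of order one and two,
    per-residue-pair occupancy and frequency-of-occurrence statistics with a
    persistence filter, apo/holo comparison tables, Kabsch superposition with
    RMSD/RMSF flexibility profiles, minimum inter-chain distance series, and
    binding/cooperativity free-energy bookkeeping from dissociation constants.
    Includes a synthetic-trajectory generator that plants water bridges with
    known per-frame occupancy schedules and emits a ground-truth manifest, so
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
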