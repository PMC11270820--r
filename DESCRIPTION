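Package: crystclass
Title: Per-Molecule Local-Environment Classification for Molecular Crystals
Version: 0.1.0
Authors@R:
    person("crystclass", "developers", email = "crystclass@example.org",
           role = c("aut", "cre"))
Description: Classifies the local environment of every molecule in a molecular
    crystal simulation snapshot as one of several polymorphs or the melt, and
    as surface or bulk. Two classifiers are provided: a small feed-forward
    network on handcrafted molecular symmetry functions built from a
    point-vector molecule representation, and a graph neural network with
    attention-based convolutions over interatomic distances and atom types
    with per-molecule max aggregation. Includes trajectory readers (extended
    XYZ and LAMMPS text dumps), periodic-boundary neighbor lists, a
    coordination-number surface/bulk rule, trajectory composition analyses
    (cluster melting, solid-solid interface migration), and a synthetic
    crystal fixture generator so the whole pipeline is testable without
    molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
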