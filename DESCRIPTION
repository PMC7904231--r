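Package: lipmap
Title: State-Dependent Protein-Lipid Interaction Mapping from Coarse-Grained Membrane Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map where and how strongly individual lipid species interact
    with a membrane-embedded pentameric receptor, and how those interactions differ
    between receptor conformational states. Computes leaflet-resolved 2D and 3D
    time-averaged lipid number densities with equal-composition isovalue
    reweighting, five-fold (C5) symmetrization and convergence diagnostics,
    per-residue continuous contact-duration statistics with repeat and subunit
    averaging, and density overlap with structurally defined ligand sites.
    Includes a fully synthetic test-bed: an asymmetric five-lipid neuronal model
    membrane builder, a static C5-symmetric pentamer, and a Brownian lipid-dynamics
    simulator with planted, state-dependent binding sites and cholesterol
    flip-flop, so every statistic can be validated against known ground truth.
    Reads and writes GRO, PDB and DCD files and OpenDX volumetric grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
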