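Package: amytrap
Title: Burial-Pattern Matching and Aggregation-Inhibition Kinetics for
    Designed Amyloid-Trapping Binders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis toolkit for designed beta-strand
    peptide-trapping binders and their effect on amyloid formation.
    Scans amyloidogenic protein sequences for windows whose burial
    pattern is compatible with a designed binding slot and threads
    matches onto template peptides; provides closed-form 1:1 binding
    models with nonlinear least-squares fitting for biolayer
    interferometry (kinetic and steady-state) and microfluidic
    diffusional sizing (exact ligand-depletion quadratic); simulates
    amyloid aggregation through nucleation-elongation-secondary-
    nucleation moment equations with monomer-sequestration and
    secondary-nucleation-modulation inhibition couplings; and infers
    inhibition mechanisms from thioflavin-T kinetic data, including a
    half-time based potency metric. A synthetic-data generator emulates
    all three assays so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
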