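Package: cationdock
Title: Constrained Carbocation Docking for Terpene Synthase Product Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for constrained docking of
    diterpene carbocation intermediates into a class I terpene synthase active
    site. Implements molecular-graph models of the isopimarenyl and abietenyl
    cations, enumeration of deprotonation sites and olefin products, prochiral
    face assignment, seeded conformer generation with energy-window and RMSD
    duplicate filtering, flat-bottom distance/angle restraint sets encoding
    mechanistic hypotheses (catalytic-base deprotonation, reactant-water
    placement per face, pyrophosphate anchoring), rigid-body pose sampling with
    a documented soft-sphere/contact scorer, a three-stage filter cascade
    (per-ligand constraint score, total-score percentile, carbocation interface
    energy percentile), and geometric product-outcome classification with
    per-product tallies. Includes synthetic receptor/ligand generators so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
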