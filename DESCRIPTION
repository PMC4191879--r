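Package: terpchannel
Title: Mechanism-Based Reaction-Channel Prediction for Triterpenoid Synthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the dominant cyclization reaction channel and plausible
    product-precursor carbocations of triterpenoid synthases from
    per-intermediate docking scores. Implements a curated library of the
    hopene (A), lupeol/dammarenyl (B) and lanosterol/protosteryl (C) reaction
    channels, hierarchical two-round channel ranking on representative
    intermediates, within-channel intermediate ranking, reaction-endpoint
    (termination) prediction with downstream product exclusion, and mutant
    delta-score classification. Also provides ligand-pose geometry utilities
    (minimal mol2/SDF/PDB readers, signed dihedrals, conformer-channel
    classification, in-place and Kabsch RMSD, core-restraint checks), a
    desk-scale constrained rigid docking stand-in with Lennard-Jones plus
    distance-dependent-dielectric Coulomb scoring, protein sequence
    similarity networks with Karlin-Altschul E-values, and seeded synthetic
    fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
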