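Package: aquapore
Title: Channel Pore, Crystal Water and Lattice-Defect Analysis for
    Aquaporin-Family Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing substrate channels of aquaporin-family
    membrane proteins from crystal structures and molecular-dynamics
    trajectories. Reads PDB/mmCIF structures into tidy atom tables and
    computes entity censuses, B-factor means, NPA-motif spacings and
    Kabsch superposition RMSDs; models and corrects the cosine intensity
    modulation caused by lattice-translocation defects and estimates the
    defect parameters from reflection data; profiles the pore radius
    along a channel axis with a deterministic maximal-inscribed-sphere
    search, optionally treating ordered waters as channel wall; detects
    hydrogen bonds, classifies channel and vestibule waters, finds
    mutually exclusive water pairs and single-file segments; places
    ideal silicic acid Si(OH)4 tetrahedra onto crystallographic water
    positions; and computes site occupancies, exchange times, permeation
    events and axial density bottlenecks from trajectories. Ships
    seeded synthetic generators for every fixture so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
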