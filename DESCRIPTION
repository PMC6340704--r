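Package: barreltopo
Title: Strand Topology and Evolutionary Alignment Analysis of Outer-Membrane Beta-Barrels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how outer-membrane beta-barrels (OMBBs)
    diversify in strand number. Assigns transmembrane strands and their
    membrane directions from backbone coordinates using phi/psi dihedrals
    and backbone hydrogen bonding; projects profile-profile alignment
    residue pairs onto strand topology; classifies alignments into
    duplication-like (C-/N-terminal anchoring, hairpin shifts) and
    non-duplication (loop-to-hairpin, large rearrangement, strand
    redirection) categories; builds E-value-thresholded similarity
    networks with component and conservation statistics; and computes
    residue-level polarity-alternation, hydropathy, and volume statistics.
    A generator of idealized barrels, sequences, and alignment scenarios
    with planted ground truth makes every stage testable without external
    structure downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
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
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
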