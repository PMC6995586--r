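Package: coevnet
Title: Coevolutionary Couplings and Structure Network Analysis of Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-track analysis of protein families combining sequence-space
    coevolution and structure-space dynamics. The sequence track computes
    reweighted, pseudocounted site frequencies from a multiple sequence
    alignment, mutual information and mean-field direct information (direct
    coupling analysis), selects top-scoring residue pairs under a minimum
    sequence-separation filter, checks them against structural contact maps,
    and models them as weighted residue graphs with Girvan-Newman community
    detection and maximal-clique enumeration. The structure track builds
    C-alpha elastic-network normal modes for wild-type and mutant models,
    derives residue cross-correlation matrices and correlation networks,
    clusters them into coarse-grained communities and profiles betweenness
    centrality. Consensus intrinsic-disorder annotation of coupled pairs and
    seed-deterministic synthetic-data generators (Potts-model alignments,
    toy chains, disorder tables) are included for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
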