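Package: dirpscan
Title: Divergent but Interacting Paralog Pairs in Protein Interaction
    Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies paralog pairs that are divergent in sequence yet
    significantly close in a protein-protein interaction network
    ("divergent but interacting" pairs, DIRPs), using Laplacian
    exponential diffusion and commute-time kernels with degree-preserving
    network randomization as the null model. Scores per-position amino
    acid conservation within the selected pair set against the alignment
    background with the BLOSUM45 substitution matrix and a permutation
    null, and maps significantly conserved positions onto protein-complex
    binding interfaces defined by solvent-accessibility loss (Shrake-Rupley
    SASA differences between bound and unbound states). Includes a
    synthetic-data generator (scale-free interactomes with planted
    shared-partner pairs, simulated family alignments and trees with
    planted conserved columns, and toy two-chain complexes) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Phylogenetics,
    StructuralPrediction, MultipleSequenceAlignment
RoxygenNote: 7.3.3
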