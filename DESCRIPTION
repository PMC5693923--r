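Package: fbgscan
Title: Epitope Scanning of Fibrinogen-Like Globe Domains for Predicted
    TLR4 Agonism
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based reconstruction of the inflammatory epitope
    shared by the fibrinogen-like globe (FBG) domains of the 24 human
    fibrinogen-related proteins (FRePs). A tenascin-C FBG reference
    annotation (cationic loop-5 ridge, loop-7 polar/hydrophobic triad,
    cationic loop-10 tail) is transferred onto target domains by global
    pairwise alignment, the three epitope features are extracted, and
    domains carrying a cationic ridge of three or more K/R residues are
    classified as predicted TLR4 activators. Includes the published
    site-directed mutant and chimera panels as executable edit
    specifications, overlapping-peptide tiling, and a synthetic-domain
    generator with ground-truth labels for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
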