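Package: rcmap
Title: Repeat Conservation Mapping of Leucine-Rich Repeat Domains
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate functional sites on leucine-rich repeat (LRR)
    protein domains from sequence alone. Solvent-exposed (non-consensus)
    residues of two or more homologous LRR domains are laid out on a generic
    repeats-by-positions surface grid, per-cell conservation is scored from
    pairwise substitution-matrix comparisons (raw and normalized), and a
    center-weighted sliding window converts cell scores into regional
    conservation scores rendered as a heat map. Includes repeat detection
    against a consensus motif with hand-curation support, an internal
    progressive aligner for unaligned input, decile-based enrichment
    statistics for ligand-contact residues, and a seeded synthetic LRR
    family generator with known conserved patches for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
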