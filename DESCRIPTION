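Package: famcons
Title: Family Conservation and Structure-Network Analysis for GST-Fold Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-site conservation analysis of protein families with a
    GST-like fold, built around the GDAP1/GST superfamily. Computes
    base-20 Shannon entropy and bidirectional Kullback-Leibler divergence
    over multiple sequence alignments projected onto a reference
    sequence, reduces sequence sets to evenly spread representatives for
    phylogeny input, and analyses crystal structures: Kabsch
    superposition with per-residue C-alpha deviation profiles,
    hydrogen-bond and salt-bridge networks between core helices,
    conservation painting onto B-factors, and overlay of disease-mutation
    sites on conserved and interacting residues. Includes synthetic
    alignment and toy-structure generators with known ground truth for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
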