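Package: structvar
Title: Structural Triage of Non-Synonymous Protein Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps non-synonymous single-nucleotide variants (missense
    substitutions) onto three-dimensional protein structures from the
    Protein Data Bank, spatially clusters the mutated residues by
    average-linkage agglomeration on C-alpha Euclidean distances, detects
    putative ligand-binding pockets with a probe-sphere (PASS-style)
    geometric method and flags pocket-proximal variants, merges
    pathogenicity annotations from local HUMSAVAR and ClinVar snapshots,
    attaches per-substitution protein-stability predictions through a
    pluggable external-tool adapter or a transparent built-in heuristic,
    and renders a self-contained HTML information page together with
    machine-readable tables and a cluster-flagged structure file for
    molecular viewers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
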