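Package: coevoscan
Title: Correlated Mutation Analysis of Protein Alignments by Mutual
    Information Z-Values and Mean-Field Direct Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects covarying residue pairs within and between proteins from
    species-matched multiple sequence alignments.  Implements pseudocount-
    corrected mutual information with Z-value normalization, a mean-field
    direct coupling analysis (DI scores) for comparison, contact-map
    benchmarking of ranked pair lists against protein structures, and
    phylogenetic robustness diagnostics (leave-species-out rank stability,
    non-sister clade support, permutation nulls, conserved-region detection).
    Includes a simulator of coevolving alignment pairs on a species tree with
    planted compensatory pairs, single-clade artifacts and sequencing errors,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    Biostrings,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
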