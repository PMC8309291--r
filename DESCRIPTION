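Package: chloronorm
Title: Standardization of Chloroplast Genome Sequences and Scaled Tree Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the quadripartite structure (LSC, IRb, SSC, IRa) of annotated
    circular chloroplast genomes, classifies how a stored sequence deviates from the
    canonical linear form (cyclic shift, inverted LSC/SSC/IRs, combinations, or
    undeterminable when inverted repeats are not annotated), and rewrites sequence and
    annotations into that form with an auditable transformation record. Also provides a
    scaled phylogenetic tree comparison suite (Robinson-Foulds, Kendall-Colijn at two
    lambda weightings, and branch score distances, each with a size-based scaling
    denominator) and a seeded synthetic plastome and tree generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'circular.R'
    'conditions.R'
    'AllClasses.R'
    'chloronorm-package.R'
    'io-fastagff.R'
    'io-genbank.R'
    'standardize.R'
    'structure.R'
    'synth.R'
    'transform.R'
    'treedist.R'
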