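Package: crypticsplice
Title: Aberrant Splice-Site Activation: Intrinsic Strength, Transposon
    Clusters and RNA Structural Probing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mutation-induced aberrant (cryptic and de
    novo) splice sites. Provides maximum-entropy and first-order Markov
    models of intrinsic splice-site strength, classification of aberrant
    sites relative to the authentic consensus footprint, exon/intron
    size-constraint statistics, RepeatMasker-based detection of nested
    transposed-element clusters and attribution of splice signals to
    element families, normalization of chemical and enzymatic RNA probing
    lanes (full-length and 2/8 rules) with differential reactivity
    testing, a simplified nearest-neighbour RNA folding engine with
    partition-function probability-of-unpaired (PU) values and
    reactivity-constrained prediction, ESRseq hexamer enhancer/silencer
    scanning, and seeded synthetic-data generators with recorded ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
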