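Package: polynac
Title: Transcription-Factor Family Characterization in Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify and characterize transcription-factor (TF)
    families in a polyploid genome with diploid relatives, with a focus on
    the NAC family. Implements TF annotation by the union of three evidence
    streams (sequence similarity, orthology, and protein-domain rules),
    reciprocal-best-hit orthology and homeolog triad retention
    classification, NAC-domain phylogenies with clade-based group label
    propagation, C-terminal-domain motif scanning with exact position
    weight matrix p-values, signed-hybrid coexpression module detection
    with topological overlap, and hypergeometric functional-term
    enrichment. A synthetic hexaploid-genome generator with full ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
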