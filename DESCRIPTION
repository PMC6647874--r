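Package: t3ssmine
Title: Mining Type III Secretion Systems in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for the in-silico characterization of bacterial
    type III secretion systems (T3SS): degenerate hrp-box promoter motif
    scanning in strand-aware upstream regions, classification of putative
    type III effectors from N-terminal sequence features, detection of T3SS
    component gene clusters by local alignment against a reference panel, and
    distance-based phylogenetics (Kimura-80 and Jukes-Cantor corrected
    distances, neighbor joining, nonparametric bootstrap, Newick output).
    Includes a synthetic-genome and alignment generator with planted,
    manifest-recorded ground truth so every stage is verifiable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
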