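Package: protospacer
Title: CRISPR sgRNA Design and Off-Target Cleavage Site Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds CRISPR/Cas9 target sites (protospacers) in input sequences
    under sense, antisense, both-strand and paired-nickase search modes;
    enumerates genome-wide potential off-target cleavage sites (POT) within a
    user-set mismatch budget under NGG/NAG PAM rules; classifies POT into three
    positional types by seed-region mismatch placement and ranks their risk;
    selects high-specificity guides by a multi-step filter cascade; designs
    cloning oligonucleotides and extracts validation-amplicon sequences
    flanking predicted cleavage sites. Includes a synthetic toy-genome
    generator with planted on- and off-target sites so the whole pipeline is
    testable without reference downloads, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
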