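Package: nbclassify
Title: Naive Bayes N-mer Classification of Metagenomic Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains naive Bayes k-mer ("N-mer") composition profiles from
    genomes or marker sequences and assigns metagenomic reads of any genomic
    origin to the maximum-likelihood taxon, with strain-level (viral) and
    species-level (fungal) training policies. Includes a 454-style
    pyrosequencing read simulator with flowgram homopolymer noise and full
    read provenance, ranked-lineage roll-up of leaf predictions to coarser
    taxonomic ranks with explicit handling of unknown ranks, multi-rank
    accuracy and classifier-agreement reports, a predominant-match novelty
    breakdown, and deterministic synthetic benchmark scenarios mixing
    in-database and novel taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
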