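Package: pangrove
Title: Pan-Genome Analysis and Comparative Queries over Annotated Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics of annotated bacterial genomes from GenBank
    flat files: identifier sanitization and sequence extraction, orthogroup
    presence/absence matrices and conservation statistics (core/pan-genome
    accumulation curves, occupancy spectra, Venn partitions, differential
    presence queries), a parser and evaluator for the KEGG module definition
    language with orthogroup-based annotation propagation, COG/KEGG functional
    category profiles, relaxed single-copy-core selection with a concatenated
    alignment and neighbor-joining species tree, genomic-region and
    Circos-style comparison data, a boolean/wildcard gene search language,
    and a single-file SQLite result store with portable archive export.
    Includes a deterministic synthetic-genome generator with planted gene
    families so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    DBI,
    RSQLite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
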