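Package: killistat
Title: Assembly Quality, Gap Context, Synteny and Sex-Chromosome Divergence for Killifish Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contiguity and gap statistics (N50/N90 with rank, maximal N-run
    detection), gene-proximal gap-context scanning against GFF3 annotations,
    reciprocal-best-hit protein homology and shared-gene chromosome matching,
    k-mer anchor dot plots, RepeatMasker landscape summaries, and phased X/Y
    fragment classification with per-gene gametolog divergence. A seeded
    synthetic diploid-genome generator with complete truth tables makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    rtracklayer,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
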