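Package: mitocomp
Title: Comparative Analysis of Ciliate Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of small, densely packed linear
    mitochondrial genomes such as those of ciliates. Reads annotated GenBank
    flat files and FASTA, scans open reading frames under non-standard genetic
    codes, summarises nucleotide composition by region class and codon
    position, quantifies codon-usage bias (relative synonymous codon
    frequencies, rare-codon counts, and Wright's effective number of codons
    generalised to the active genetic code), estimates pairwise divergence and
    Nei-Gojobori Ka/Ks with a Mann-Whitney contrast of gene classes, builds
    neighbor-joining trees with bootstrap support and maps compositional (GC3)
    shifts onto them, and detects intragenic minisatellites. A seeded
    synthetic-data generator produces genomes, codon alignments, and strain
    sets with machine-readable ground truth so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
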