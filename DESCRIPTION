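Package: codonica
Title: Codon Usage Bias of Single- and Multiple-Exon Genes via Internal
    Correspondence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies protein-coding genes from a genome FASTA and GFF3
    annotation into single-exon and multiple-exon classes, computes per-gene
    codon usage indices (effective number of codons, codon adaptation index,
    relative synonymous codon usage, synonymous third-position base usage and
    positional GC content), and partitions total codon usage variability with
    an internal correspondence analysis that decomposes chi-square inertia
    into between/within gene-class by between/within amino-acid components.
    Includes ENC-plot and neutrality-plot selection diagnostics, size-matched
    subsampling and label-permutation significance tests, Nei-Gojobori (1986)
    Ka/Ks estimation on codon-aligned ortholog pairs, and a seeded synthetic
    genome generator with controllable between-class synonymous codon
    preference divergence for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
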