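Package: xadist
Title: Reference-Independent Comparative Metagenomics by Cross-Assembly
    Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares metagenomic samples without a reference database by
    accounting reads in a cross-assembly: a single de novo assembly built
    from the pooled reads of two or more samples.  Parses consed-style ACE
    assembly files together with per-sample FASTA/FASTQ read files (sequence
    information may be stripped), tabulates per-contig read counts for each
    sample, and computes four pairwise distance formulas based on shared
    cross-contigs and read fractions, plus a dinucleotide odds-ratio
    signature distance as a reference-independent baseline.  Distance
    matrices are summarised as BioNJ cladograms (Newick output, with and
    without branch lengths) or, for two or three samples, as XY/XYZ scatter
    and triangle plots.  A synthetic-data module generates genome pools,
    community read sets with pyrosequencing-like errors, and a toy k-mer
    single-linkage cross-assembler with exact ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
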