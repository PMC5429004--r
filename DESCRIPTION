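Package: fabatools
Title: Genome-Resource Analyses for Faba Bean Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses for building genome resources in faba bean
    (Vicia faba) from short-read sequencing: compartment read accounting
    across organellar, transcriptome and repeat-element references;
    coverage-based unigene verification (peak/breadth/depth classification);
    splice-point detection from softclip clusters of unspliced genomic reads
    aligned to a spliced transcriptome; extension of linkage-marker locus
    sequences with de novo contigs under a 95/95 identity-coverage
    criterion; organelle single-nucleotide variant calling with codon-level
    effect annotation; and windowed percent-identity homology maps between
    organelle gene sets of related legumes. Includes a deterministic
    simulator that generates every input with known truth, so the whole
    pipeline runs and is tested at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
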