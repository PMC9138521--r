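Package: rsnpdb
Title: Regulatory SNP Annotation in Plant Promoters by Allele-Specific PWM Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts allele-specific transcription factor binding sites in
    gene promoter regions and classifies the effect of each single nucleotide
    polymorphism (SNP) on each binding site as a gain, loss, score-change or
    no-change. Given a reference genome (FASTA), gene annotations (GFF3), a
    SNP catalog (VCF or GVF) and a position weight matrix (PWM) library
    (TRANSFAC-dialect flat file), the pipeline maps SNPs to promoter windows
    around transcription start sites, builds 51-bp reference and alternate
    search sequences, scans both alleles with MATCH-style core and matrix
    similarity scoring, flags regulatory SNPs (rSNPs), and materializes the
    results in a four-table relational store with query, export and summary
    statistics, including the distribution of rSNP distances to the TSS.
    A deterministic synthetic-fixture generator with planted, ground-truth
    binding-site effects makes every stage testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tools,
    vcfR,
    DBI,
    RSQLite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
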