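Package: idseqr
Title: Immuno-Detection by Sequencing: Barcode Demultiplexing, UMI
    Counting and Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of immuno-detection by
    sequencing (ID-seq) experiments, in which antibodies carry
    double-stranded DNA tags with an antibody-dedicated barcode and a
    unique molecular identifier (UMI), and wells are identified by a
    second PCR-added barcode. The package parses triple-barcoded FASTQ
    reads with error-tolerant barcode matching, deduplicates on UMIs to
    build antibody-by-well count matrices, estimates median-of-ratios
    size factors, fits per-antibody negative-binomial regressions with
    likelihood-ratio tests for treatment effects, and provides
    screen-level analytics: principal-component aggregation of signed
    log10 p-values, decile phenotype contrasts, probe-set assignment by
    robust outlier statistics, permutation-based set enrichment, and
    probe-set molecular profiles. Ground-truthed simulators for reads,
    count matrices and screen matrices make every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    MASS
Config/testthat/edition: 3
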