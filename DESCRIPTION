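Package: damescan
Title: Differential Allele-Specific Methylation Region Detection from
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-sample allele-specific methylation (ASM) scores
    from bisulfite-sequencing reads, either from read counts of nearby CpG
    pairs (a weighted log-odds score with Beta-probability shrinkage) or by
    partitioning reads at heterozygous SNPs, and detects regions of
    differential allele-specific methylation (DAMEs) between two sample
    groups. Per-position moderated t-statistics with empirical-Bayes
    variance shrinkage are combined with within-cluster loess smoothing;
    candidate regions are assigned FDR-controlled p-values either by
    permutation of group labels (pooled null area distribution) or by Simes
    combination of per-position p-values. Includes a synthetic-data module
    that emulates read-level biallelic methylation and score-level matrices
    with spiked group effects, for calibration and power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
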