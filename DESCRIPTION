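Package: MAMscreen
Title: SNP-Guided Detection of Monoallelic DNA-Methylation from
    Enrichment-Based Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects monoallelically methylated loci from enrichment-based
    DNA-methylation sequencing (MethylCap-seq/MBD-seq) allele counts at known
    SNP positions. Because enrichment assays only capture methylated alleles,
    stable monoallelic methylation makes heterozygous individuals look
    homozygous; the package tests each locus for a heterozygote deficit
    relative to Hardy-Weinberg expectations with a coverage-conditioned
    permutation null, after iterative Bayesian correction of sequencing
    errors. It includes a two-stage Monte-Carlo screen with
    Benjamini-Hochberg FDR calling, chromosome-matched functional-enrichment
    analysis, bisulfite (per-allele chi-square) and allele-specific-expression
    (exact binomial) validation statistics, and a synthetic-data generator
    with ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: Epigenetics, DNAMethylation, SNP, StatisticalMethod, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
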