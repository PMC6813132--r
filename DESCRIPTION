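Package: asmQTL
Title: Allele-Specific Methylation Assisted mQTL Mapping for Bisulfite
    Sequencing Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Methylation quantitative trait locus (mQTL) mapping for
    bisulfite sequencing studies using an over-dispersed binomial mixed
    model fitted by penalized quasi-likelihood. The joint model combines
    per-individual methylated/total read counts across all individuals
    with allele-specific counts from heterozygotes, so that the
    within-individual allele contrast boosts power to detect cis genetic
    effects on CpG methylation. Includes individual-level-only and
    allele-only special cases, beta-binomial and M-value linear mixed
    model baselines, a full simulation engine for power and calibration
    studies, permutation-based empirical false discovery rate
    estimation, quality-control filters for SNP-CpG pairs, and CpG
    island/shore/shelf/open-sea annotation with enrichment tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
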