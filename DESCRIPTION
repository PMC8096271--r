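Package: vntrscope
Title: Minisatellite VNTR Copy-Number Genotyping and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of minisatellite variable number tandem
    repeats (VNTRs, pattern sizes 7-126 bp) from short sequencing reads.
    Implements cyclic (wraparound) local dynamic-programming alignment for
    repeat copy-number estimation, per-sample allele calling encoded as
    copies gained/lost (CGL) with read support (SP) and VCF output,
    detectability rules for read-length-limited genotyping, cohort
    statistics (common/private VNTR classification, heterozygosity,
    gain/loss spectrum, tumor/normal loss of heterozygosity), validation
    procedures (Mendelian trio consistency, cross-platform allele
    agreement, long-read confirmation), population-specific allele
    discovery (one-sided Fisher exact tests with FDR control, PCA and
    decision-tree ancestry classification, virtual gel rendering), and a
    VNTR-gene-expression association scan (covariate residualization with
    surrogate hidden factors and one-way ANOVA). A synthetic-cohort
    generator produces reference repeat sets, diploid multi-population
    genotypes, trios, error-bearing reads, and expression matrices with
    planted effects, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
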