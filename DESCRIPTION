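Package: autozyg
Title: Runs of Homozygosity, Genomic Inbreeding Coefficients and
    Inbreeding-Depression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying inbreeding depression with SNP-array
    genotypes. Simulates consanguineous cohorts by gene-dropping founder
    haplotypes through pedigrees with recombination (tracking true
    identity-by-descent segments), calls runs of homozygosity (ROH) with a
    sliding-window algorithm, computes genomic inbreeding estimators
    (F_ROH, F_SNP, F_GRM, SNP homozygosity outside ROH), fits per-cohort
    effect models for quantitative and binary traits (univariate,
    partitioned by ROH length, bivariate, within-sibling designs), and
    combines cohorts by fixed-effect inverse-variance meta-analysis with
    bootstrap ratio summaries. Reads and writes PLINK ped/map and
    bed/bim/fam genotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
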