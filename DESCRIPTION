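Package: tissueqtl
Title: Cross-Tissue cis-eQTL Mapping with Cohort QC, FDR Control and Power
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for mapping cis-acting expression quantitative
    trait loci (eQTLs) at GWAS-implicated SNPs across blood, frontal cortex
    and cerebellum. Implements genotype- and sample-level quality control
    (call-rate/MAF/Hardy-Weinberg filters, LD pruning, IBS/MDS ancestry
    outlier removal, method-of-moments relatedness exclusion), GWAS-catalog
    inclusion filtering, expression detection and probe-level filtering,
    covariate-adjusted allelic-dosage regression in a 500 kb cis window with
    Benjamini-Hochberg FDR control, cross-tissue eQTL sharing classification
    with conditional proxy-SNP analysis, and closed-form plus Monte-Carlo
    power calculations under the additive model. A synthetic-cohort generator
    with a fully known planted eQTL architecture makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
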