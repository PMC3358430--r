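# Shared configuration for the analysis workflow. Every numbered script
# sources this file, so the whole run is reproducible from one seed.
#
# The synthetic cohort emulates the statistical structure of a two-series
# eQTL study: a few thousand genome-wide background markers for sample QC,
# a GWAS-implicated SNP subset for cis mapping, three tissues (blood,
# frontal cortex, cerebellum), and a planted eQTL architecture containing
# shared, blood-specific, brain-specific and expression-restricted effects.

library(tissueqtl)

RESULTS_DIR <- file.path("results")
# cohort-scale intermediates (VCF, expression matrices) are bulky and
# regenerable, so they live under scratch/; results/ holds summary tables
COHORT_DIR <- file.path("scratch", "cohort")

analysis_config <- function(seed = 20260923L) {
  list(
    seed = seed,
    n_samples = 200L,          # a cohort two-fifths the blood series
    n_snps = 6000L,            # background markers for IBS/pi-hat QC
    n_gwas_snps = 30L,         # trait-associated SNPs carried to cis maps
    maf_range = c(0.1, 0.5),
    dosage_rsq = 0.95,         # imputation quality above the 0.3 filter
    n_duplicate_pairs = 1L,    # planted cryptic duplicate
    n_outlier_samples = 2L,    # planted ancestry outliers
    effects = list(
      # shared across all three tissues
      planted_effect("@snp2", "@probe2", eqtl_tissues(), 1.0),
      planted_effect("@snp3", "@probe3", eqtl_tissues(), 0.8),
      # blood-specific (probe expressed everywhere)
      planted_effect("@snp5", "@probe5", "blood", 1.0),
      # brain-specific
      planted_effect("@snp7", "@probe7",
                     c("frontal_cortex", "cerebellum"), 1.0),
      # blood-restricted expression: only assessable in blood
      planted_effect("@snp9", "@probe9", "blood", 1.0,
                     expressed_in = "blood"),
      # brain-restricted expression
      planted_effect("@snp11", "@probe11", "cerebellum", 1.0,
                     expressed_in = c("frontal_cortex", "cerebellum"))
    ),
    out_dir = COHORT_DIR
  )
}
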