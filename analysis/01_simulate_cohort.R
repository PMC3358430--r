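#!/usr/bin/env Rscript
# Simulate the synthetic multi-tissue cohort and write its stage inputs
# (dosage VCF, expression/detection TSVs, probe BED, covariates) under
# results/cohort/. The planted-effect truth table is saved for later
# stages to score against.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

spec <- cohort_spec(cfg$n_samples, cfg$n_snps, cfg$maf_range,
                    seed = cfg$seed,
                    n_duplicate_pairs = cfg$n_duplicate_pairs,
                    n_outlier_samples = cfg$n_outlier_samples,
                    dosage_rsq = cfg$dosage_rsq)
cohort <- simulate_cohort(spec, effects = cfg$effects,
                          n_probes = cfg$n_gwas_snps)

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
write_dosage_vcf(cohort$genotypes$dosage, cohort$genotypes$snps,
                 file.path(COHORT_DIR, "dosages.vcf"))
write_probe_bed(cohort$probes, file.path(COHORT_DIR, "probes.bed"))
write.table(cohort$covariates, file.path(COHORT_DIR, "covariates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (tis in names(cohort$expression)) {
  write_matrix_tsv(cohort$expression[[tis]]$expr,
                   file.path(COHORT_DIR, paste0("expression_", tis, ".tsv")),
                   "probe_id")
  write_matrix_tsv(cohort$expression[[tis]]$detection_p,
                   file.path(COHORT_DIR, paste0("detection_", tis, ".tsv")),
                   "probe_id")
}
truth <- do.call(rbind, lapply(cohort$effects, function(ef) data.frame(
  snp_id = ef$snp_id, probe_id = ef$probe_id, beta = ef$beta,
  tissue_set = paste(ef$tissue_set, collapse = ","),
  expressed_in = paste(ef$expressed_in, collapse = ","))))
write.table(truth, file.path(COHORT_DIR, "planted_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d samples x %d markers (%d GWAS SNPs, %d probes, 3 tissues)\n",
  cfg$n_samples, cfg$n_snps, cfg$n_gwas_snps, nrow(cohort$probes)))
cat(sprintf("Planted %d eQTL effects; truth table at %s\n",
            length(cohort$effects),
            file.path(COHORT_DIR, "planted_effects.tsv")))
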