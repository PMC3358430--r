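#!/usr/bin/env Rscript
# Genotype- and sample-level QC on the simulated cohort, reading the VCF
# written by 01_simulate_cohort.R: SNP filters (call rate < 95%,
# MAF < 0.01, HWE p < 1e-7, imputation r2 < 0.3), LD pruning
# (50-SNP window, step 5, r2 > 0.2), IBS/MDS ancestry outliers (> 3 SD on
# C1/C2) and relatedness exclusion (pi-hat > 0.15).

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

vcf <- read_dosage_vcf(file.path(COHORT_DIR, "dosages.vcf"))
dos <- vcf$dosage

# SNP annotation with QC statistics recomputed from the genotypes
g <- hard_genotypes(dos)
ann <- vcf$snps
ann$maf <- colMeans(g) / 2
ann$call_rate <- 1
ann$hwe_p <- vapply(seq_len(ncol(g)), function(j) {
  cnt <- tabulate(g[, j] + 1L, 3)
  hwe_exact_test(cnt[1], cnt[2], cnt[3])
}, numeric(1))
ann$imputed <- TRUE
ann$imputation_rsq <- cfg$dosage_rsq

snp_qc <- filter_snps(ann)
dos <- dos[, snp_qc$kept$snp_id]

pruned <- ld_prune(dos)
bg <- dos[, pruned$kept]
mds <- ibs_mds(bg, sd_threshold = 3)
rel <- relatedness_exclude(bg, threshold = 0.15)

dir.create(RESULTS_DIR, showWarnings = FALSE)
write.table(snp_qc$reasons, file.path(RESULTS_DIR, "qc_snp_reasons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
comp <- data.frame(sample_id = rownames(mds$components), mds$components,
                   outlier = mds$outliers)
write.table(comp, file.path(RESULTS_DIR, "qc_mds_components.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
flagged <- rel$pairs[rel$pairs$pihat > 0.15, ]
write.table(flagged, file.path(RESULTS_DIR, "qc_related_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("SNP QC: %d of %d markers kept (%d dropped)\n",
            nrow(snp_qc$kept), nrow(ann), nrow(snp_qc$dropped)))
cat(sprintf("LD pruning: %d of %d markers retained for sample QC\n",
            length(pruned$kept), ncol(dos)))
cat(sprintf("MDS outliers (> 3 SD on C1/C2): %s\n",
            paste(comp$sample_id[comp$outlier], collapse = " ")))
cat(sprintf("Related pairs above pi-hat 0.15: %d; excluded: %s\n",
            nrow(flagged), paste(rel$excluded, collapse = " ")))
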