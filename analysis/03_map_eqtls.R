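#!/usr/bin/env Rscript
# Run the full pipeline (QC -> catalog -> expression QC -> cis mapping ->
# consensus -> sharing classification) on the seeded cohort and score the
# sharing calls against the planted truth.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()
res <- run_pipeline(cfg)

for (tis in names(res$results))
  write.table(res$results[[tis]],
              file.path(RESULTS_DIR, paste0("eqtl_", tis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$consensus, file.path(RESULTS_DIR, "eqtl_consensus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$sharing, file.path(RESULTS_DIR, "sharing_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(res$manifest, file.path(RESULTS_DIR, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cnt <- res$manifest$counts
cat(sprintf("Samples: %d simulated -> %d after QC\n",
            cnt$samples_simulated, cnt$samples_after_qc))
cat(sprintf("Cis pairs: %d; tested per tissue: %s\n", cnt$cis_pairs,
            paste(sprintf("%s=%d", names(cnt$pairs_tested),
                          unlist(cnt$pairs_tested)), collapse = " ")))
calls <- res$sharing
nonnull <- calls[calls$call != "null", c("snp_id", "probe_id", "call")]
cat("Non-null sharing calls:\n")
print(nonnull, row.names = FALSE)

# score against the planted architecture
truth <- read.delim(file.path(COHORT_DIR, "planted_effects.tsv"))
truth$expected <- ifelse(
  truth$expressed_in == "blood", "blood_restricted_expression",
  ifelse(!grepl("blood", truth$expressed_in), "brain_restricted_expression",
  ifelse(truth$tissue_set == "blood", "blood_specific",
  ifelse(grepl("blood", truth$tissue_set), "shared_all", "brain_specific"))))
m <- merge(truth, calls[, c("snp_id", "probe_id", "call")],
           by = c("snp_id", "probe_id"))
cat(sprintf("Planted effects recovered with the expected call: %d of %d\n",
            sum(m$call == m$expected), nrow(truth)))
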