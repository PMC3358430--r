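#!/usr/bin/env Rscript
# Cross-tissue comparison layer: percentile-rank expression profiles,
# direction-of-effect consistency for shared eQTLs, tissue-by-trait-class
# count tables and proportion tests.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()
res <- run_pipeline(cfg)

# percentile-rank profiles of mean and variance per tissue
expr_list <- lapply(res$cohort$expression, function(e) e$expr)
ranks <- rank_profile_table(expr_list, res$detected)
write.table(ranks, file.path(RESULTS_DIR, "rank_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
wide <- reshape(ranks[, c("probe_id", "tissue", "mean_rank")],
                idvar = "probe_id", timevar = "tissue",
                direction = "wide")
cat(sprintf(
  "Mean-rank Spearman correlations: blood~fc %.2f, blood~cb %.2f, fc~cb %.2f\n",
  cor(wide$mean_rank.blood, wide$mean_rank.frontal_cortex, method = "spearman"),
  cor(wide$mean_rank.blood, wide$mean_rank.cerebellum, method = "spearman"),
  cor(wide$mean_rank.frontal_cortex, wide$mean_rank.cerebellum,
      method = "spearman")))

# direction consistency across tissues for eQTLs shared by blood and brain
calls <- res$sharing
sig <- calls[calls$call == "shared_all", ]
if (nrow(sig)) {
  b <- as.matrix(sig[, grep("^beta_", names(sig))])
  dc <- direction_consistency(b)
  cat(sprintf(
    "Direction of effect consistent in %d of %d shared eQTLs\n",
    dc$n_consistent, nrow(sig)))
}

# trait-class count table over the consensus track
cc <- res$consensus
cc$trait_class <- res$catalog$trait_class[match(cc$snp_id,
                                                res$catalog$snp_id)]
tab <- count_table(cc)
write.table(tab, file.path(RESULTS_DIR, "counts_by_trait_class.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

# compare the significant fraction between blood and cerebellum
get <- function(tis) {
  sel <- tab$tissue == tis
  c(sig = sum(tab$n_signif[sel]), tested = sum(tab$n_tested[sel]))
}
a <- get("blood"); b <- get("cerebellum")
pt <- suppressWarnings(
  proportion_tests(a["sig"], a["tested"], b["sig"], b["tested"]))
cat(sprintf(
  "Blood %d/%d vs cerebellum %d/%d significant: z = %.2f, p = %.3f (chi2 %.2f)\n",
  a["sig"], a["tested"], b["sig"], b["tested"], pt$z, pt$p_z, pt$chisq))
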