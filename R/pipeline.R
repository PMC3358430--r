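#' Validate a pipeline run configuration
#'
#' Checks thresholds against their legal ranges before any stage runs.
#'
#' @param config Named list; recognized entries (all optional, thresholds
#'   default to the standard study values): `seed`, `n_samples`, `n_snps`
#'   (genome-wide background markers used for sample QC), `n_gwas_snps`
#'   (the leading subset carried into cis mapping), `maf_range`,
#'   `dosage_rsq`, `n_duplicate_pairs`, `n_outlier_samples`,
#'   `callrate_min` (0.95), `maf_min` (0.01), `hwe_p_min` (1e-7),
#'   `rsq_min` (0.3), `pihat_max` (0.15), `mds_sd` (3), `cis_window`
#'   (5e5), `min_hom` (3), `detection_p` (0.01), `detection_frac` (0.95),
#'   `fdr_q` (0.05), `tissues`, `effects`, `out_dir`.
#' @return The config filled with defaults; stops on an invalid value.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(seed = 1L, n_samples = 100L, n_snps = 4000L,
                   n_gwas_snps = 40L, maf_range = c(0.1, 0.5),
                   dosage_rsq = 0.95,
                   n_duplicate_pairs = 0L, n_outlier_samples = 0L,
                   callrate_min = 0.95, maf_min = 0.01, hwe_p_min = 1e-7,
                   rsq_min = 0.3, pihat_max = 0.15, mds_sd = 3,
                   cis_window = 500000L, min_hom = 3L, detection_p = 0.01,
                   detection_frac = 0.95, fdr_q = 0.05,
                   tissues = eqtl_tissues(), effects = list(),
                   out_dir = NULL)
  # modifyList would recurse into (and drop) the unnamed effects list
  effects <- if (!is.null(config$effects)) config$effects
             else defaults$effects
  config$effects <- defaults$effects <- NULL
  cfg <- utils::modifyList(defaults, config)
  cfg$effects <- effects
  chk <- function(ok, what)
    if (!ok) stop("invalid config: ", what, call. = FALSE)
  chk(cfg$maf_min >= 0 && cfg$maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  chk(cfg$callrate_min >= 0 && cfg$callrate_min <= 1,
      "callrate_min must be in [0, 1]")
  chk(cfg$hwe_p_min >= 0 && cfg$hwe_p_min <= 1, "hwe_p_min must be in [0, 1]")
  chk(cfg$rsq_min >= 0 && cfg$rsq_min <= 1, "rsq_min must be in [0, 1]")
  chk(cfg$pihat_max >= 0 && cfg$pihat_max <= 1, "pihat_max must be in [0, 1]")
  chk(cfg$fdr_q > 0 && cfg$fdr_q < 1, "fdr_q must be in (0, 1)")
  chk(cfg$detection_frac >= 0 && cfg$detection_frac <= 1,
      "detection_frac must be in [0, 1]")
  chk(cfg$cis_window > 0, "cis_window must be positive")
  chk(cfg$n_gwas_snps <= cfg$n_snps, "n_gwas_snps must be <= n_snps")
  chk(all(cfg$tissues %in% eqtl_tissues()), "unknown tissue label")
  cfg
}

#' Run the full synthetic-cohort eQTL pipeline
#'
#' Executes the stages in order: cohort simulation; genotype QC (call
#' rate/MAF/HWE/imputation-quality filters) on all markers; sample QC
#' (LD pruning, IBS/MDS ancestry outlier removal, relatedness exclusion)
#' on the genome-wide background markers; GWAS-catalog simulation and
#' inclusion filtering over the GWAS-SNP subset; expression QC (detection
#' and probe exclusions); per-tissue covariate-adjusted dosage regression
#' in the cis window with BH-FDR; consensus extraction; sharing
#' classification; trait-class count tables; and the cohort power summary.
#' As in the real study design, sample-level QC draws on all genotyped
#' markers while eQTL mapping is restricted to the trait-associated SNP
#' subset. Re-running with the same config reproduces identical results.
#'
#' @param config A config list (see [validate_config()]).
#' @return A list with `cohort`, `snp_qc`, `sample_qc`, `catalog`,
#'   `detected`, `pairs`, `results` (per-tissue eQTL tables), `consensus`,
#'   `restricted`, `sharing`, `counts_by_class`, `power`, and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  spec <- cohort_spec(cfg$n_samples, cfg$n_snps, cfg$maf_range,
                      seed = cfg$seed,
                      n_duplicate_pairs = cfg$n_duplicate_pairs,
                      n_outlier_samples = cfg$n_outlier_samples,
                      dosage_rsq = cfg$dosage_rsq)
  cohort <- simulate_cohort(spec, effects = cfg$effects,
                            n_probes = cfg$n_gwas_snps,
                            tissues = cfg$tissues)
  geno <- cohort$genotypes

  # --- genotype QC ---
  snp_qc <- filter_snps(geno$snps, cfg$callrate_min, cfg$maf_min,
                        cfg$hwe_p_min, cfg$rsq_min)
  kept_snps <- snp_qc$kept$snp_id
  dos <- geno$dosage[, kept_snps, drop = FALSE]

  # --- sample QC on the genome-wide background ---
  pruned <- ld_prune(dos)
  bg <- dos[, pruned$kept, drop = FALSE]
  mds <- ibs_mds(bg, sd_threshold = cfg$mds_sd)
  rel <- relatedness_exclude(bg, threshold = cfg$pihat_max)
  drop_samples <- union(rownames(dos)[mds$outliers], rel$excluded)
  keep_samples <- setdiff(rownames(dos), drop_samples)
  dos <- dos[keep_samples, , drop = FALSE]
  cov <- cohort$covariates[match(keep_samples, cohort$covariates$sample_id), ]
  cov$C1 <- mds$components[keep_samples, 1]
  cov$C2 <- mds$components[keep_samples, 2]

  # --- GWAS-catalog stage: the SNPs eQTL mapping is restricted to ---
  gwas_ids <- intersect(
    geno$snps$snp_id[seq_len(cfg$n_gwas_snps)], kept_snps)
  cat_rec <- simulate_catalog(length(gwas_ids), fraction_passing = 1,
                              seed = cfg$seed + 7L)
  cat_rec$snp_id <- gwas_ids
  cat_rec$chromosome <- "1"
  cat_rec$position <- geno$snps$position[match(gwas_ids, geno$snps$snp_id)]
  cat_flt <- filter_catalog(cat_rec)
  cat_kept <- annotate_traits(
    cat_flt$kept,
    stats::setNames(cat_flt$kept$trait_class_truth, cat_flt$kept$trait))
  snp_ann <- snp_qc$kept[snp_qc$kept$snp_id %in% cat_kept$snp_id, ]

  # --- expression QC and cis pairing ---
  pe <- probe_exclusions(cohort$probes, snp_ann)
  probes_ok <- cohort$probes[cohort$probes$probe_id %in% pe$kept, ]
  pairs <- pair_cis(snp_ann, probes_ok, window = cfg$cis_window)
  detected <- lapply(cohort$expression, function(e)
    intersect(detection_filter(e$detection_p, cfg$detection_p,
                               cfg$detection_frac), pe$kept))

  # --- per-tissue eQTL mapping ---
  results <- lapply(cfg$tissues, function(tis) {
    e <- cohort$expression[[tis]]
    map_tissue_eqtls(pairs, dos, e$expr[, keep_samples, drop = FALSE],
                     cov, detected[[tis]], tis, min_hom = cfg$min_hom,
                     q_thresh = cfg$fdr_q)
  })
  names(results) <- cfg$tissues

  cons <- if (length(results) >= 2) consensus_set(results, cfg$fdr_q)
          else list(consensus = results[[1]],
                    restricted = results[[1]][0, ])
  sharing <- if (all(eqtl_tissues() %in% cfg$tissues))
    classify_sharing(cons$consensus, cons$restricted, q_thresh = cfg$fdr_q)
  else NULL

  # --- trait-class accounting and power summary ---
  class_map <- stats::setNames(cat_kept$trait_class, cat_kept$snp_id)
  counts <- NULL
  if (nrow(cons$consensus)) {
    cc <- cons$consensus
    cc$trait_class <- unname(class_map[cc$snp_id])
    counts <- count_table(cc)
  }
  pow <- data.frame(
    n = cfg$n_samples,
    maf = 0.2, Z = 0.5,
    power = analytic_power(power_spec(cfg$n_samples, 0.2, 0.5)))

  manifest <- list(
    seed = cfg$seed,
    thresholds = cfg[c("callrate_min", "maf_min", "hwe_p_min", "rsq_min",
                       "pihat_max", "mds_sd", "cis_window", "min_hom",
                       "detection_p", "detection_frac", "fdr_q")],
    counts = list(
      samples_simulated = spec$n_samples,
      samples_after_qc = length(keep_samples),
      snps_simulated = spec$n_snps,
      snps_after_qc = length(kept_snps),
      snps_after_pruning = length(pruned$kept),
      gwas_snps = length(gwas_ids),
      gwas_snps_kept = nrow(cat_kept),
      probes_simulated = nrow(cohort$probes),
      probes_after_exclusions = length(pe$kept),
      probes_detected = lapply(detected, length),
      cis_pairs = nrow(pairs),
      pairs_tested = lapply(results, function(r) sum(r$status == "tested")),
      pairs_significant = lapply(results, function(r) sum(r$significant)),
      consensus_pairs = length(unique(paste(cons$consensus$snp_id,
                                            cons$consensus$probe_id)))
    )
  )

  out <- list(cohort = cohort, snp_qc = snp_qc,
              sample_qc = list(mds = mds, relatedness = rel,
                               excluded = drop_samples),
              catalog = cat_kept, detected = detected, pairs = pairs,
              results = results,
              consensus = cons$consensus, restricted = cons$restricted,
              sharing = sharing, counts_by_class = counts, power = pow,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cohort, cfg)
  out
}

# stage outputs as plain text so any stage can be re-run on real data
write_pipeline_outputs <- function(out, cohort, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_dosage_vcf(cohort$genotypes$dosage, cohort$genotypes$snps,
                   p("dosages.vcf"))
  write_probe_bed(cohort$probes, p("probes.bed"))
  utils::write.table(cohort$covariates, p("covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tis in names(cohort$expression)) {
    write_matrix_tsv(cohort$expression[[tis]]$expr,
                     p(paste0("expression_", tis, ".tsv")), "probe_id")
    write_matrix_tsv(cohort$expression[[tis]]$detection_p,
                     p(paste0("detection_", tis, ".tsv")), "probe_id")
  }
  utils::write.table(out$snp_qc$reasons, p("snp_qc_reasons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tis in names(out$results))
    utils::write.table(out$results[[tis]], p(paste0("eqtl_", tis, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$consensus, p("consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(out$sharing))
    utils::write.table(out$sharing, p("sharing_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(NULL)
}
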