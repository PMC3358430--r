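#' Specify a synthetic genotyping cohort
#'
#' A `cohort_spec` fixes everything the genotype simulator needs: sample and
#' SNP counts, the minor-allele-frequency range SNPs are drawn from, the
#' per-SNP imputation quality (the MACH-style dosage r-squared), and the
#' number of planted related pairs and ancestry outliers. The seed fully
#' determines the generated cohort.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 numeric, the (lower, upper) bound of the uniform
#'   MAF draw; bounds must lie in (0, 0.5]. The default lower bound 0.01
#'   matches the common-variant floor used throughout the QC stage.
#' @param seed Integer seed; the same seed reproduces the cohort byte for
#'   byte.
#' @param n_duplicate_pairs Number of planted duplicate sample pairs
#'   (identical hard genotypes; downstream pi-hat = 1).
#' @param n_outlier_samples Number of planted ancestry outliers whose allele
#'   frequencies are shifted by `outlier_shift`.
#' @param dosage_rsq Imputation quality in `[0, 1]`: the squared correlation
#'   between the continuous dosage and the underlying hard genotype. 1 means
#'   dosages equal hard genotypes.
#' @param outlier_shift Allele-frequency shift applied to planted outliers.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_snps, maf_range = c(0.01, 0.5),
                        seed = 1L, n_duplicate_pairs = 0L,
                        n_outlier_samples = 0L, dosage_rsq = 1.0,
                        outlier_shift = 0.2) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("invalid cohort spec: n_samples must be >= 2", call. = FALSE)
  if (!is.numeric(n_snps) || n_snps < 1)
    stop("invalid cohort spec: n_snps must be >= 1", call. = FALSE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("invalid cohort spec: maf_range must be within (0, 0.5]", call. = FALSE)
  if (dosage_rsq < 0 || dosage_rsq > 1)
    stop("invalid cohort spec: dosage_rsq must be in [0, 1]", call. = FALSE)
  if (2 * n_duplicate_pairs + n_outlier_samples >= n_samples)
    stop("invalid cohort spec: duplicates + outliers must be < n_samples",
         call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 seed = as.integer(seed),
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 n_outlier_samples = as.integer(n_outlier_samples),
                 dosage_rsq = as.numeric(dosage_rsq),
                 outlier_shift = as.numeric(outlier_shift)),
            class = "cohort_spec")
}

#' Simulate HWE genotypes and imputed dosages
#'
#' Hard genotypes are drawn per SNP from Hardy-Weinberg proportions at that
#' SNP's MAF. Continuous dosages emulate imputation output: with per-SNP
#' quality `r2 = dosage_rsq`, the dosage is the shrinkage mixture
#' `d = r2 * g + (1 - r2) * 2p + e`, with `e` Gaussian and scaled so that
#' `cor(d, g)^2 = r2` and `var(d) = r2 * 2p(1-p)` — the MACH convention in
#' which the reported r-squared equals the dosage-to-binomial variance ratio.
#' Dosages are clamped to `[0, 2]`.
#'
#' Planted duplicate pairs copy hard genotypes (and dosages) exactly; the
#' second member of pair `k` replaces sample `n - k + 1`. Planted ancestry
#' outliers (the last `n_outlier_samples` non-duplicate samples) are drawn at
#' allele frequencies shifted by `outlier_shift`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with:
#'   \describe{
#'     \item{dosage}{`n_samples x n_snps` numeric matrix of dosages in `[0,2]`.}
#'     \item{genotype}{integer matrix of hard genotypes (minor-allele counts).}
#'     \item{snps}{data frame of SNP annotation: `snp_id`, `chromosome`,
#'       `position`, `minor_allele`, `major_allele`, `maf`, `call_rate`,
#'       `hwe_p`, `imputed`, `imputation_rsq`.}
#'     \item{sample_ids}{character vector.}
#'     \item{duplicate_pairs}{two-column matrix of planted duplicate indices.}
#'     \item{outlier_samples}{integer vector of planted outlier indices.}
#'   }
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_snps
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])

  g <- vapply(seq_len(m), function(j) {
    stats::rbinom(n, size = 2L, prob = maf[j])
  }, integer(n))
  g <- matrix(g, nrow = n)

  out_idx <- integer(0)
  if (spec$n_outlier_samples > 0) {
    # outliers occupy the last slots before any duplicate copies
    avail <- seq_len(n - spec$n_duplicate_pairs)
    out_idx <- utils::tail(avail, spec$n_outlier_samples)
    p_shift <- pmin(pmax(maf + spec$outlier_shift, 0.01), 0.99)
    for (i in out_idx) g[i, ] <- stats::rbinom(m, 2L, p_shift)
  }

  dup <- matrix(integer(0), ncol = 2)
  if (spec$n_duplicate_pairs > 0) {
    a <- seq_len(spec$n_duplicate_pairs)
    b <- n - seq_len(spec$n_duplicate_pairs) + 1L
    dup <- cbind(a, b)
    g[b, ] <- g[a, , drop = FALSE]
  }

  r2 <- spec$dosage_rsq
  if (r2 >= 1) {
    d <- g * 1.0
  } else {
    v <- 2 * maf * (1 - maf)
    sd_e <- sqrt(pmax(r2 * v * (1 - r2), 0))
    e <- matrix(stats::rnorm(n * m), nrow = n) * rep(sd_e, each = n)
    d <- r2 * g + (1 - r2) * rep(2 * maf, each = n) + e
    if (nrow(dup) > 0) d[dup[, 2], ] <- d[dup[, 1], , drop = FALSE]
    d <- pmin(pmax(d, 0), 2)
  }

  hwe <- vapply(seq_len(m), function(j) {
    tab <- tabulate(g[, j] + 1L, nbins = 3L)
    if (sum(tab) == 0) return(1.0)
    hwe_exact_test(tab[1], tab[2], tab[3])
  }, numeric(1))

  # SNPs spaced 1 Mb apart so each sits in its own cis neighbourhood
  snps <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chromosome = "1",
    position = seq_len(m) * 1e6,
    minor_allele = "A",
    major_allele = "G",
    maf = colMeans(g) / 2,
    call_rate = 1.0,
    hwe_p = hwe,
    imputed = r2 < 1,
    imputation_rsq = r2,
    stringsAsFactors = FALSE
  )
  colnames(d) <- colnames(g) <- snps$snp_id
  ids <- sprintf("S%04d", seq_len(n))
  rownames(d) <- rownames(g) <- ids
  list(dosage = d, genotype = g, snps = snps, sample_ids = ids,
       duplicate_pairs = dup, outlier_samples = as.integer(out_idx))
}

#' Simulate sample covariates
#'
#' Generates the covariates the regression model adjusts for: age at death,
#' gender, post-mortem interval (PMI), tissue bank, hybridization batch, and
#' two placeholder MDS components (downstream code typically replaces C1/C2
#' with components computed from the genotypes themselves).
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param n_banks,n_batches Number of categorical levels.
#' @return A data frame with one row per sample and no missing values.
#' @export
simulate_covariates <- function(n_samples, seed = 1L, n_banks = 3L,
                                n_batches = 4L) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    age_at_death = round(stats::rnorm(n_samples, 75, 10), 1),
    gender = stats::rbinom(n_samples, 1L, 0.5),
    pmi = round(stats::rgamma(n_samples, shape = 4, scale = 3), 1),
    tissue_bank = factor(sample(paste0("bank", seq_len(n_banks)),
                                n_samples, replace = TRUE)),
    hybridization_batch = factor(sample(paste0("batch", seq_len(n_batches)),
                                        n_samples, replace = TRUE)),
    C1 = stats::rnorm(n_samples, 0, 0.01),
    C2 = stats::rnorm(n_samples, 0, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Declare a planted cis-eQTL effect
#'
#' @param snp_id,probe_id Identifiers that must exist in the cohort.
#' @param tissue_set Character subset of the tissues in which the SNP drives
#'   expression of the probe.
#' @param beta Per-minor-allele effect, in expression-SD units.
#' @param expressed_in Tissues in which the probe is detectable at all; must
#'   contain `tissue_set`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(snp_id, probe_id, tissue_set, beta,
                           expressed_in = eqtl_tissues()) {
  if (!all(tissue_set %in% expressed_in))
    stop("tissue_set must be a subset of expressed_in", call. = FALSE)
  if (!is.finite(beta)) stop("beta must be finite", call. = FALSE)
  structure(list(snp_id = snp_id, probe_id = probe_id,
                 tissue_set = tissue_set, beta = beta,
                 expressed_in = expressed_in),
            class = "planted_effect")
}

#' Tissues modelled by the pipeline
#' @return Character vector of the three tissue labels.
#' @export
eqtl_tissues <- function() c("blood", "frontal_cortex", "cerebellum")

#' Simulate a tissue expression matrix with planted eQTL effects
#'
#' Each probe's log2 expression is
#' `y = mu + beta * dose * [tissue in tissue_set] + covariate loadings +
#' N(0, sigma^2)` noise. Covariate loadings default to small (0.1 SD)
#' contributions from age, PMI and batch so that covariate adjustment is
#' exercised without dominating the genetic signal. Detection p-values are
#' drawn uniform below 0.01 for probes expressed in the tissue and uniform
#' on (0.5, 1) otherwise, so downstream detection filtering drops
#' non-expressed probes.
#'
#' @param dosages Numeric sample-by-SNP dosage matrix (from
#'   [simulate_genotypes()]).
#' @param effects List of [planted_effect()] objects.
#' @param covariates Covariate data frame from [simulate_covariates()].
#' @param tissue One of [eqtl_tissues()].
#' @param probe_ids Character vector of all probe ids on the simulated array.
#' @param expressed_probes Probes expressed in this tissue (default: all).
#'   Probes named by an effect follow the effect's `expressed_in` instead.
#' @param seed Integer seed.
#' @param sigma Residual SD of expression noise (beta is therefore in
#'   residual-SD units by default).
#' @param covariate_sd Common SD of the age/PMI/batch loadings.
#' @param probe_means Per-probe baseline log2 level (default: 8 for all).
#'   Passing the same vector for several tissues makes their expression
#'   profiles comparable, emulating probe-to-probe abundance differences
#'   that are preserved across tissues.
#' @return A list with `expr` (probes x samples log2 intensities),
#'   `detection_p` (same shape), `tissue`.
#' @export
simulate_expression <- function(dosages, effects, covariates, tissue,
                                probe_ids, expressed_probes = probe_ids,
                                seed = 1L, sigma = 1.0, covariate_sd = 0.1,
                                probe_means = rep(8, length(probe_ids))) {
  if (!tissue %in% eqtl_tissues())
    stop("unknown tissue label: ", tissue, call. = FALSE)
  for (ef in effects) {
    if (!ef$snp_id %in% colnames(dosages))
      stop("effect refers to unknown snp_id: ", ef$snp_id, call. = FALSE)
    if (!ef$probe_id %in% probe_ids)
      stop("effect refers to unknown probe_id: ", ef$probe_id, call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(dosages)
  np <- length(probe_ids)

  expressed <- probe_ids %in% expressed_probes
  names(expressed) <- probe_ids
  for (ef in effects) expressed[ef$probe_id] <- tissue %in% ef$expressed_in

  age_c <- as.numeric(scale(covariates$age_at_death))
  pmi_c <- as.numeric(scale(covariates$pmi))
  batch_eff <- stats::rnorm(nlevels(covariates$hybridization_batch), 0, 1)
  batch_c <- batch_eff[as.integer(covariates$hybridization_batch)]

  expr <- probe_means + matrix(stats::rnorm(np * n, mean = 0, sd = sigma),
                               nrow = np,
                               dimnames = list(probe_ids, rownames(dosages)))
  load <- covariate_sd * (age_c + pmi_c + batch_c)
  expr <- expr + matrix(load, nrow = np, ncol = n, byrow = TRUE)

  for (ef in effects) {
    if (tissue %in% ef$tissue_set) {
      expr[ef$probe_id, ] <- expr[ef$probe_id, ] +
        ef$beta * dosages[, ef$snp_id]
    }
  }

  det <- matrix(NA_real_, nrow = np, ncol = n,
                dimnames = dimnames(expr))
  for (i in seq_len(np)) {
    det[i, ] <- if (expressed[i]) stats::runif(n, 0, 0.0099)
                else stats::runif(n, 0.5, 1)
  }
  list(expr = expr, detection_p = det, tissue = tissue)
}

#' Simulate GWAS-catalog records with known filter outcomes
#'
#' Each record either passes all six inclusion criteria or violates one
#' chosen criterion, and the planted pass label is recorded so the catalog
#' filter can be verified exactly. Trait classes (blood/brain/other) are
#' drawn with the given probabilities.
#'
#' @param n_records Number of records.
#' @param fraction_passing Fraction of records planted to pass every
#'   criterion.
#' @param trait_class_probs Named numeric of class probabilities, summing
#'   to 1, over blood/brain/other.
#' @param seed Integer seed.
#' @return A data frame of catalog records with planted `passes` label and
#'   `violated` reason.
#' @export
simulate_catalog <- function(n_records, fraction_passing = 0.7,
                             trait_class_probs = c(blood = 0.22, brain = 0.08,
                                                   other = 0.70),
                             seed = 1L) {
  if (abs(sum(trait_class_probs) - 1) > 1e-8)
    stop("trait_class_probs must sum to 1", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_records)
  passes <- stats::runif(n) < fraction_passing
  criteria <- c("p", "initial_n", "replication_n", "n_snps", "ancestry", "raf")
  violated <- ifelse(passes, "",
                     sample(criteria, n, replace = TRUE))

  cls <- sample(names(trait_class_probs), n, replace = TRUE,
                prob = trait_class_probs)
  traits <- paste0("trait_", cls, "_", seq_len(n))

  rec <- data.frame(
    snp_id = sprintf("rs%06d", sample.int(999999L, n)),
    chromosome = as.character(sample.int(22L, n, replace = TRUE)),
    position = sample.int(2e8L, n),
    trait = traits,
    discovery_p = 10^stats::runif(n, -30, -8.5),
    initial_n = sample(1500:50000, n, replace = TRUE),
    replication_n = sample(600:20000, n, replace = TRUE),
    n_snps_in_study = sample(150000:2500000, n, replace = TRUE),
    ancestry = "European",
    risk_allele_freq = round(stats::runif(n, 0.05, 0.95), 3),
    is_binomial = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in which(!passes)) {
    switch(violated[i],
      p = rec$discovery_p[i] <- 10^stats::runif(1, -7.2, -3),
      initial_n = rec$initial_n[i] <- sample(100:1000, 1),
      replication_n = rec$replication_n[i] <- sample(50:500, 1),
      n_snps = rec$n_snps_in_study[i] <- sample(5000:100000, 1),
      ancestry = rec$ancestry[i] <- "East Asian",
      raf = rec$risk_allele_freq[i] <- round(stats::runif(1, 5e-4, 0.009), 4))
  }
  rec$trait_class_truth <- cls
  rec$passes <- passes
  rec$violated <- violated
  rec
}

#' Simulate a complete multi-tissue cohort
#'
#' Convenience wrapper tying genotypes, covariates, per-tissue expression,
#' probe annotation and the planted-effect truth table into one bundle, for
#' end-to-end runs and tests.
#'
#' @param spec A [cohort_spec()].
#' @param effects List of [planted_effect()]s. Probe ids referenced must be
#'   among `probe_ids`.
#' @param n_probes Number of probes on the simulated array (default places
#'   one probe per SNP plus extras).
#' @param tissues Tissues to simulate.
#' @param sigma,covariate_sd Passed to [simulate_expression()].
#' @return A list with `genotypes` (the [simulate_genotypes()] bundle),
#'   `covariates`, `expression` (named list per tissue), `probes` (BED-style
#'   annotation data frame), and `effects`.
#' @export
simulate_cohort <- function(spec, effects = list(), n_probes = spec$n_snps,
                            tissues = eqtl_tissues(), sigma = 1.0,
                            covariate_sd = 0.1) {
  geno <- simulate_genotypes(spec)
  cov <- simulate_covariates(spec$n_samples, seed = spec$seed + 1L)
  probe_ids <- sprintf("ILMN_%07d", seq_len(n_probes))

  # re-point effects given symbolic probe/snp references like "@snp3"/"@probe3"
  effects <- lapply(effects, function(ef) {
    if (grepl("^@snp", ef$snp_id))
      ef$snp_id <- geno$snps$snp_id[as.integer(sub("@snp", "", ef$snp_id))]
    if (grepl("^@probe", ef$probe_id))
      ef$probe_id <- probe_ids[as.integer(sub("@probe", "", ef$probe_id))]
    ef
  })

  # probes sit 1 kb from their index-matched SNP so cis pairing is trivial
  pos0 <- pmin(seq_len(n_probes), spec$n_snps) * 1e6 + 1000
  probes <- data.frame(
    chromosome = "1",
    start = pos0, end = pos0 + 50L,
    probe_id = probe_ids,
    quality_flag = "good",
    stringsAsFactors = FALSE
  )

  set.seed(spec$seed + 50L)
  probe_means <- stats::rnorm(n_probes, mean = 8, sd = 2)
  expr <- lapply(tissues, function(tis) {
    simulate_expression(geno$dosage, effects, cov, tis, probe_ids,
                        seed = spec$seed + 100L + match(tis, eqtl_tissues()),
                        sigma = sigma, covariate_sd = covariate_sd,
                        probe_means = probe_means)
  })
  names(expr) <- tissues
  list(genotypes = geno, covariates = cov, expression = expr,
       probes = probes, effects = effects)
}
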