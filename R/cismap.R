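#' Pair SNPs with probes in a cis window
#'
#' A SNP and a probe are paired iff they lie on the same chromosome and the
#' distance between the SNP position and the probe reference point — the
#' midpoint of the 50-mer interval — is at most `window` (inclusive).
#' Chromosome labels are normalized ("chr1" and "1" match).
#'
#' @param snps Data frame with `snp_id`, `chromosome`, `position` (1-based).
#' @param probes Data frame with `probe_id`, `chromosome`, `start`, `end`
#'   (0-based half-open).
#' @param window Cis window in bp (default 500 kb).
#' @return Data frame `snp_id`, `probe_id`, `distance`.
#' @export
pair_cis <- function(snps, probes, window = 500000L) {
  norm_chr <- function(x) sub("^chr", "", tolower(as.character(x)))
  sc <- norm_chr(snps$chromosome)
  pc <- norm_chr(probes$chromosome)
  ref <- (probes$start + probes$end) / 2
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    sel <- pc == sc[i] & abs(ref - snps$position[i]) <= window
    if (any(sel)) {
      out[[i]] <- data.frame(snp_id = snps$snp_id[i],
                             probe_id = probes$probe_id[sel],
                             distance = abs(ref[sel] - snps$position[i]),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(0), probe_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  res
}

#' Minor-homozygote filter
#'
#' A SNP passes iff at least `min_count` samples are minor-allele
#' homozygotes (hard genotype 2, from rounded dosages or called genotypes).
#'
#' @param dosage Numeric dosage vector for one SNP.
#' @param min_count Minimum minor-homozygote count (default 3).
#' @return Logical: TRUE if the SNP can be tested.
#' @export
min_homozygote_filter <- function(dosage, min_count = 3L) {
  sum(hard_genotypes(dosage) == 2L) >= min_count
}

#' Build the covariate design matrix
#'
#' Expands the covariate table into numeric model columns: age, gender,
#' PMI, MDS components C1/C2 as-is; tissue bank and hybridization batch as
#' indicator columns against the most frequent level.
#'
#' @param covariates Covariate data frame (see [simulate_covariates()]);
#'   NULL gives a zero-column matrix.
#' @param n Number of samples (required when `covariates` is NULL).
#' @return Numeric matrix with one row per sample.
#' @export
covariate_design <- function(covariates, n = nrow(covariates)) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  num_cols <- intersect(c("age_at_death", "gender", "pmi", "C1", "C2"),
                        names(covariates))
  X <- as.matrix(covariates[, num_cols, drop = FALSE])
  for (fc in intersect(c("tissue_bank", "hybridization_batch"),
                       names(covariates))) {
    f <- as.factor(covariates[[fc]])
    f <- stats::relevel(f, ref = names(which.max(table(f))))
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(fc, "_", levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  X
}

#' Covariate-adjusted dosage regression for one SNP:probe pair
#'
#' Ordinary least squares of expression on `[intercept, dose, covariates]`.
#' Reports the dose coefficient, its standard error, t statistic and the
#' two-sided p-value from the t distribution with `n_used - k` degrees of
#' freedom. Samples with any missing value are dropped pairwise. A rank-
#' deficient design involving the dose column (for example, dose constant
#' after sample exclusions) yields status "collinear" with undefined p,
#' not an error.
#'
#' @param y Numeric expression vector.
#' @param dose Numeric dosage vector, same length.
#' @param covariates Covariate data frame or pre-built numeric matrix
#'   (see [covariate_design()]); NULL for no adjustment.
#' @return List with `beta`, `se`, `t_stat`, `p`, `n_used`, `df`, `status`
#'   ("tested" or "collinear").
#' @export
fit_eqtl <- function(y, dose, covariates = NULL) {
  C <- if (is.matrix(covariates)) covariates
       else covariate_design(covariates, n = length(y))
  X <- cbind(`(Intercept)` = 1, dose = dose, C)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  yy <- y[ok]
  n_used <- length(yy)
  k <- ncol(X)
  bad <- list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
              p = NA_real_, n_used = n_used, df = n_used - k,
              status = "collinear")
  if (n_used < k + 1) return(bad)   # need at least 1 residual df
  qr_x <- qr(X)
  if (qr_x$rank < k) return(bad)
  fit <- stats::lm.fit(X, yy)
  df <- n_used - k
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv_dd <- chol2inv(qr.R(qr_x))[2, 2]
  beta <- unname(fit$coefficients["dose"])
  se <- sqrt(sigma2 * XtXinv_dd)
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(beta = beta, se = se, t_stat = t_stat, p = p, n_used = n_used,
       df = df, status = "tested")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (q-values), capped at 1 and monotone in the
#' sorted order, with significance flags at `q < q_thresh`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q_thresh Significance cut (default 0.05, i.e. 5% FDR).
#' @return List with `q` (adjusted values) and `significant` (logical).
#' @export
bh_fdr <- function(pvals, q_thresh = 0.05) {
  if (length(pvals) == 0)
    return(list(q = numeric(0), significant = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = !is.na(q) & q < q_thresh)
}

#' Conditional dosage regression on a proxy SNP
#'
#' Refits the eQTL model with the proxy SNP's dosage appended as a
#' covariate, reporting both the marginal and the conditional dose
#' association. If the dose and proxy are collinear the conditional fit is
#' flagged "collinear". Conditioning on a proxy that tags the causal
#' haplotype absorbs the signal (conditional p rises toward 1); an
#' irrelevant proxy leaves the dose effect essentially unchanged.
#'
#' @param y Expression vector.
#' @param dose Dosage vector for the SNP under test.
#' @param proxy_dose Dosage vector for the proxy SNP (same samples).
#' @param covariates Covariate data frame/matrix or NULL.
#' @return List with `marginal` and `conditional`, each a [fit_eqtl()]
#'   result.
#' @export
conditional_fit <- function(y, dose, proxy_dose, covariates = NULL) {
  stopifnot(length(proxy_dose) == length(dose))
  marginal <- fit_eqtl(y, dose, covariates)
  C <- if (is.matrix(covariates)) covariates
       else covariate_design(covariates, n = length(y))
  conditional <- fit_eqtl(y, dose, cbind(C, proxy = proxy_dose))
  list(marginal = marginal, conditional = conditional)
}

#' Map cis-eQTLs for one tissue
#'
#' Runs the full per-tissue engine: for each cis pair whose probe passed
#' detection filtering and whose SNP passes the minor-homozygote filter,
#' fits the covariate-adjusted dosage regression; then adjusts the tested
#' p-values with BH within the tissue. Pairs excluded beforehand are
#' retained with status `excluded_undetected` or `excluded_min_hom`
#' so that consensus extraction can see the full accounting.
#'
#' @param pairs Data frame from [pair_cis()].
#' @param dosage Sample-by-SNP dosage matrix.
#' @param expr Probe-by-sample expression matrix for the tissue.
#' @param covariates Covariate data frame/matrix or NULL.
#' @param detected Character vector of detected probe ids for this tissue.
#' @param tissue Tissue label attached to the results.
#' @param min_hom Minor-homozygote minimum (default 3).
#' @param q_thresh FDR significance cut.
#' @return Data frame: `snp_id`, `probe_id`, `tissue`, `n_used`, `beta`,
#'   `se`, `t_stat`, `p`, `q`, `significant`, `status`, `distance`.
#' @export
map_tissue_eqtls <- function(pairs, dosage, expr, covariates, detected,
                             tissue, min_hom = 3L, q_thresh = 0.05) {
  C <- if (is.matrix(covariates)) covariates
       else covariate_design(covariates, n = nrow(dosage))
  snp_ok <- vapply(unique(pairs$snp_id), function(s)
    min_homozygote_filter(dosage[, s], min_hom), logical(1))
  res <- pairs
  res$tissue <- tissue
  res$n_used <- NA_integer_
  res$beta <- res$se <- res$t_stat <- res$p <- res$q <- NA_real_
  res$significant <- FALSE
  res$status <- ifelse(!(res$probe_id %in% detected), "excluded_undetected",
                       ifelse(!snp_ok[res$snp_id], "excluded_min_hom",
                              "tested"))
  test_idx <- which(res$status == "tested")
  for (i in test_idx) {
    f <- fit_eqtl(expr[res$probe_id[i], ], dosage[, res$snp_id[i]], C)
    res$n_used[i] <- f$n_used
    res$beta[i] <- f$beta
    res$se[i] <- f$se
    res$t_stat[i] <- f$t_stat
    res$p[i] <- f$p
    if (f$status != "tested") res$status[i] <- f$status
  }
  tested <- which(res$status == "tested")
  if (length(tested)) {
    adj <- bh_fdr(res$p[tested], q_thresh)
    res$q[tested] <- adj$q
    res$significant[tested] <- adj$significant
  }
  res[, c("snp_id", "probe_id", "tissue", "n_used", "beta", "se", "t_stat",
          "p", "q", "significant", "status", "distance")]
}

#' Extract the cross-tissue consensus set
#'
#' Inner-joins per-tissue eQTL results on (snp_id, probe_id) over pairs
#' with status "tested" in every tissue; the complement (pairs tested in at
#' least one but not all tissues) is returned for tissue-restricted
#' analysis. Within each track, BH adjustment is recomputed per tissue over
#' that track's tested pairs, mirroring the two separate multiple-testing
#' families.
#'
#' @param results_by_tissue Named list of [map_tissue_eqtls()] data frames
#'   (>= 2 tissues).
#' @param q_thresh FDR significance cut for the recomputed adjustment.
#' @return List with `consensus` (long data frame restricted to consensus
#'   pairs, q re-adjusted within the consensus family) and `restricted`
#'   (pairs tested in a strict subset of tissues, q re-adjusted within the
#'   restricted family; includes a `tested_in` column).
#' @export
consensus_set <- function(results_by_tissue, q_thresh = 0.05) {
  stopifnot(length(results_by_tissue) >= 2)
  keys <- lapply(results_by_tissue, function(r)
    paste(r$snp_id, r$probe_id, sep = ":")[r$status == "tested"])
  all_keys <- unique(unlist(keys))
  in_all <- Reduce(intersect, keys)
  some <- setdiff(all_keys, in_all)

  readjust <- function(df) {
    if (nrow(df) == 0) return(df)
    df$q <- NA_real_
    df$significant <- FALSE
    for (tis in unique(df$tissue)) {
      sel <- df$tissue == tis & df$status == "tested"
      if (any(sel)) {
        adj <- bh_fdr(df$p[sel], q_thresh)
        df$q[sel] <- adj$q
        df$significant[sel] <- adj$significant
      }
    }
    df
  }

  long <- do.call(rbind, results_by_tissue)
  rownames(long) <- NULL
  key <- paste(long$snp_id, long$probe_id, sep = ":")
  consensus <- readjust(long[key %in% in_all, , drop = FALSE])
  restricted <- long[key %in% some, , drop = FALSE]
  if (nrow(restricted)) {
    rk <- paste(restricted$snp_id, restricted$probe_id, sep = ":")
    tested_in <- tapply(restricted$tissue[restricted$status == "tested"],
                        rk[restricted$status == "tested"],
                        function(x) paste(sort(x), collapse = ","))
    restricted$tested_in <- as.vector(tested_in[rk])
    restricted <- readjust(restricted)
  } else {
    restricted$tested_in <- character(0)
  }
  list(consensus = consensus, restricted = restricted)
}
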