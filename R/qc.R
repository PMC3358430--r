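#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions: conditioning on the
#' observed allele counts, the probability of each possible heterozygote
#' count is `P(het) = C * 2^het * n! / (n_AA! n_Aa! n_aa!)`, and the p-value
#' is the sum of probabilities of configurations no more probable than the
#' observed one. This is the convention used at the genotype-QC filtering
#' step (a chi-squared approximation misbehaves at low minor-allele counts);
#' no mid-p correction is applied.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @return Exact p-value in `[0, 1]`.
#' @examples
#' hwe_exact_test(1, 0, 1)   # 1/3
#' hwe_exact_test(0, 2, 0)   # 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) %% 1 != 0))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_minor <- 2 * n_aa + n_Aa   # minor allele count (relabel if needed)
  if (n_minor > n) n_minor <- 2 * n - n_minor
  # feasible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log unnormalized probability for each het count
  homr <- (n_minor - hets) / 2          # rare-homozygote count
  homc <- n - hets - homr               # common-homozygote count
  logp <- hets * log(2) + lgamma(n + 1) -
    lgamma(homc + 1) - lgamma(hets + 1) - lgamma(homr + 1)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs_p <- prob[match(n_Aa, hets)]
  if (is.na(obs_p)) stop("heterozygote count inconsistent with allele count",
                         call. = FALSE)
  min(1, sum(prob[prob <= obs_p + 1e-12 * obs_p]))
}

#' Filter SNPs on call rate, MAF, HWE and imputation quality
#'
#' Drops a SNP iff its call rate is below 0.95, its MAF is below 0.01, or
#' its HWE p-value is below 1e-7; imputed SNPs are additionally dropped if
#' their imputation r-squared is below 0.3 (the MAF floor applies to them
#' too). All comparisons are strict, matching the original filter wording.
#' Records with missing required fields are dropped with reason "malformed".
#'
#' @param records Data frame with columns `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `imputed`, `imputation_rsq`.
#' @param callrate_min,maf_min,hwe_p_min,rsq_min Thresholds (defaults are
#'   the pipeline's standard values).
#' @return List with `kept` (data frame), `dropped` (data frame) and
#'   `reasons` (data frame `snp_id`, `reason` — one row per violated
#'   criterion, reasons in `{callrate, maf, hwe, rsq, malformed}`).
#' @export
filter_snps <- function(records, callrate_min = 0.95, maf_min = 0.01,
                        hwe_p_min = 1e-7, rsq_min = 0.3) {
  req <- c("snp_id", "call_rate", "maf", "hwe_p", "imputed")
  if (!all(req %in% names(records)))
    stop("records must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    bad <- character(0)
    core <- c(r$call_rate, r$maf, r$hwe_p)
    if (anyNA(core) || (isTRUE(r$imputed) && is.na(r$imputation_rsq))) {
      bad <- "malformed"
    } else {
      if (r$call_rate < callrate_min) bad <- c(bad, "callrate")
      if (r$maf < maf_min) bad <- c(bad, "maf")
      if (r$hwe_p < hwe_p_min) bad <- c(bad, "hwe")
      if (isTRUE(r$imputed) && r$imputation_rsq < rsq_min)
        bad <- c(bad, "rsq")
    }
    reasons[[i]] <- bad
  }
  drop <- lengths(reasons) > 0
  reason_df <- data.frame(
    snp_id = rep(records$snp_id, lengths(reasons)),
    reason = unlist(reasons),
    stringsAsFactors = FALSE
  )
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE],
       reasons = reason_df)
}

#' Sliding-window LD pruning on squared dosage correlation
#'
#' Within each 50-SNP window the pruner scans pairs in positional order and
#' greedily removes the later SNP of any still-kept pair whose squared
#' dosage correlation exceeds the threshold; the window then advances by
#' `step_snps`. SNPs must already be ordered by chromosome and position.
#' Zero-variance SNPs cannot be correlated and are kept (and flagged).
#'
#' @param dosages Sample-by-SNP numeric matrix with SNP ids as column names.
#' @param chromosomes Optional per-SNP chromosome labels; windows never span
#'   chromosomes. Default: all one chromosome.
#' @param window_snps,step_snps,r2_threshold Window size, advance step and
#'   r-squared cutoff.
#' @return List with `kept` (character SNP ids), `removed`, and
#'   `zero_variance` (flagged ids).
#' @export
ld_prune <- function(dosages, chromosomes = NULL, window_snps = 50L,
                     step_snps = 5L, r2_threshold = 0.2) {
  m <- ncol(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (is.null(chromosomes)) chromosomes <- rep("1", m)
  vars <- apply(dosages, 2, stats::var)
  zero_var <- vars <= 0 | is.na(vars)
  keep <- rep(TRUE, m)
  for (chr in unique(chromosomes)) {
    idx <- which(chromosomes == chr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window_snps - 1L, length(idx))]
      live <- win[keep[win] & !zero_var[win]]
      if (length(live) > 1) {
        r2 <- suppressWarnings(
          stats::cor(dosages[, live, drop = FALSE])^2)
        for (a in seq_along(live)) {
          i <- live[a]
          if (!keep[i]) next
          for (b in seq_along(live)) {
            if (b <= a) next
            j <- live[b]
            if (keep[j] && !is.na(r2[a, b]) && r2[a, b] > r2_threshold)
              keep[j] <- FALSE
          }
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  list(kept = ids[keep], removed = ids[!keep],
       zero_variance = ids[zero_var])
}

#' Round dosages to hard genotypes
#'
#' Nearest-integer rounding with ties (x.5) rounded up, so a dosage of 0.5
#' becomes a heterozygote and 1.5 a minor homozygote.
#'
#' @param dosages Numeric matrix or vector of dosages in `[0, 2]`.
#' @return Integer genotypes in `{0, 1, 2}`.
#' @export
hard_genotypes <- function(dosages) {
  g <- floor(dosages + 0.5)
  storage.mode(g) <- "integer"
  pmin(pmax(g, 0L), 2L)
}

#' IBS distance matrix from hard genotypes
#'
#' Pairwise identity-by-state distance: per SNP the shared-allele fraction
#' between two samples is `1 - |g_i - g_j| / 2` (0, 1/2 or 1); the distance
#' is one minus its mean over SNPs.
#'
#' @param genotypes Sample-by-SNP integer matrix of hard genotypes.
#' @return A symmetric `n x n` distance matrix with zero diagonal.
#' @export
ibs_distance <- function(genotypes) {
  cnt <- ibs_state_counts(as.matrix(genotypes))
  d <- (cnt$N1 + 2 * cnt$N0) / (2 * cnt$m)
  dimnames(d) <- list(rownames(genotypes), rownames(genotypes))
  diag(d) <- 0
  d
}

# pairwise IBS-state counts via indicator-matrix crossproducts:
# N0 = loci with opposite homozygotes, N1 = het vs hom, N2 = identical state
ibs_state_counts <- function(g) {
  A0 <- (g == 0L) * 1; A1 <- (g == 1L) * 1; A2 <- (g == 2L) * 1
  N0 <- tcrossprod(A0, A2)
  N0 <- N0 + t(N0)
  N1 <- tcrossprod(A1, A0 + A2)
  N1 <- N1 + t(N1)
  m <- ncol(g)
  list(N0 = N0, N1 = N1, N2 = m - N0 - N1, m = m)
}

#' IBS clustering / MDS with ancestry-outlier flags
#'
#' Classical multidimensional scaling (eigendecomposition of the
#' double-centred squared IBS distance matrix, via [stats::cmdscale()])
#' produces component scores C1, C2, ...; a sample is flagged as an ancestry
#' outlier iff any of its leading components lies more than `sd_threshold`
#' standard deviations from the component mean, with mean and SD computed
#' over a designated reference subset (standing in for reference-panel
#' samples; default all samples).
#'
#' @param dosages Sample-by-SNP dosage matrix (rounded internally to hard
#'   genotypes; the IBS step precedes imputation).
#' @param n_components Number of MDS components to return and screen.
#' @param sd_threshold Outlier cut in reference-subset SD units.
#' @param reference Indices (or logical mask) of the reference subset.
#' @return List with `components` (n x k matrix, columns C1..Ck ordered by
#'   decreasing eigenvalue), `outliers` (logical vector), `eigenvalues`.
#' @export
ibs_mds <- function(dosages, n_components = 2L, sd_threshold = 3,
                    reference = seq_len(nrow(dosages))) {
  n <- nrow(dosages)
  if (n < 3) stop("ibs_mds requires at least 3 samples", call. = FALSE)
  g <- hard_genotypes(dosages)
  d <- ibs_distance(g)
  if (all(d == 0)) {
    comp <- matrix(0, n, n_components,
                   dimnames = list(rownames(dosages),
                                   paste0("C", seq_len(n_components))))
    return(list(components = comp, outliers = rep(FALSE, n),
                eigenvalues = rep(0, n_components)))
  }
  mds <- stats::cmdscale(d, k = n_components, eig = TRUE)
  comp <- mds$points
  colnames(comp) <- paste0("C", seq_len(ncol(comp)))
  ref <- comp[reference, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  dev <- abs(sweep(comp, 2, mu)) > sd_threshold * rep(sdv, each = n)
  list(components = comp, outliers = rowSums(dev) > 0,
       eigenvalues = mds$eig[seq_len(n_components)])
}

#' Method-of-moments relatedness estimation and exclusion
#'
#' Estimates pairwise pi-hat (the proportion of alleles shared identical by
#' descent, `P(IBD=2) + P(IBD=1)/2`) from identity-by-state counts and
#' cohort allele frequencies, following the method-of-moments scheme used in
#' standard genotype QC: per-SNP expected IBS-state probabilities given
#' IBD state are accumulated from allele frequencies, then the observed IBS
#' counts are inverted for P(IBD = 0, 1, 2), each clamped to `[0, 1]`.
#' For every pair whose pi-hat exceeds `threshold` (strictly), one member is
#' excluded: the one with the lower call rate, ties broken toward the later
#' sample id.
#'
#' @param dosages Sample-by-SNP dosage matrix (rounded to hard genotypes).
#' @param threshold Pi-hat exclusion cut (strict `>`).
#' @param call_rates Optional per-sample call rates used to pick which pair
#'   member to exclude (default: all 1, so the later id is excluded).
#' @return List with `pairs` (data frame `id1`, `id2`, `ibs_distance`,
#'   `pihat`), `excluded` (character sample ids).
#' @export
relatedness_exclude <- function(dosages, threshold = 0.15,
                                call_rates = NULL) {
  n <- nrow(dosages)
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 2)
    return(list(pairs = data.frame(id1 = character(0), id2 = character(0),
                                   ibs_distance = numeric(0),
                                   pihat = numeric(0)),
                excluded = character(0)))
  if (is.null(call_rates)) call_rates <- rep(1, n)
  g <- hard_genotypes(dosages)
  p <- colMeans(g) / 2          # frequency of the dosage-counted allele
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p

  # expected IBS-state probabilities given IBD state, summed over SNPs
  e0_ibs0 <- sum(2 * p^2 * q^2)
  e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- ncol(g)

  cnt <- ibs_state_counts(g)
  ut <- which(upper.tri(cnt$N0), arr.ind = TRUE)
  n0 <- cnt$N0[ut]; n1 <- cnt$N1[ut]; n2 <- cnt$N2[ut]
  p0 <- pmin(pmax(if (e0_ibs0 > 0) n0 / e0_ibs0 else 0, 0), 1)
  p1 <- pmin(pmax(if (e1_ibs1 > 0) (n1 - p0 * e0_ibs1) / e1_ibs1 else 0,
                  0), 1)
  p2 <- pmin(pmax((n2 - p0 * e0_ibs2 - p1 * e1_ibs2) / m, 0), 1)
  pihat <- pmin(pmax(p2 + p1 / 2, 0), 1)
  pairs <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                      ibs_distance = (n1 + 2 * n0) / (2 * m),
                      pihat = pihat, stringsAsFactors = FALSE)

  excluded <- character(0)
  flagged <- pairs[pairs$pihat > threshold, , drop = FALSE]
  if (nrow(flagged)) {
    flagged <- flagged[order(-flagged$pihat), , drop = FALSE]
    for (r in seq_len(nrow(flagged))) {
      a <- flagged$id1[r]; b <- flagged$id2[r]
      if (a %in% excluded || b %in% excluded) next
      cr_a <- call_rates[match(a, ids)]
      cr_b <- call_rates[match(b, ids)]
      drop <- if (cr_a < cr_b) a
              else if (cr_b < cr_a) b
              else max(a, b)      # tie: later sample id
      excluded <- c(excluded, drop)
    }
  }
  list(pairs = pairs, excluded = excluded)
}
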