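#' Classify cross-tissue eQTL sharing
#'
#' For consensus pairs (tested in blood and both brain regions) the call is
#' based on the per-tissue FDR-adjusted q-values:
#' \itemize{
#'   \item `shared_all` — significant in blood and, under the default
#'     strict mode, in both brain regions (relaxed mode: at least one);
#'   \item `blood_specific` — significant in blood only;
#'   \item `brain_specific` — significant in at least one brain region but
#'     not in blood;
#'   \item `null` — significant nowhere.
#' }
#' Restricted pairs (probe detected only in a subset of tissues) that are
#' significant where testable are called `blood_restricted_expression` or
#' `brain_restricted_expression` by the tissue that detected the probe.
#'
#' @param consensus Consensus data frame from [consensus_set()] (long, one
#'   row per pair per tissue, with `q` and `status`).
#' @param restricted Optional restricted data frame from [consensus_set()].
#' @param q_thresh Significance cut on q (default 0.05).
#' @param strict_shared If TRUE (default), `shared_all` requires both brain
#'   regions significant; if FALSE, either one suffices.
#' @param blood_tissue,brain_tissues Tissue labels.
#' @return Data frame `snp_id`, `probe_id`, `call`, plus per-tissue
#'   `q_<tissue>` and `beta_<tissue>` columns.
#' @export
classify_sharing <- function(consensus, restricted = NULL, q_thresh = 0.05,
                             strict_shared = TRUE,
                             blood_tissue = "blood",
                             brain_tissues = c("frontal_cortex",
                                               "cerebellum")) {
  tiss <- c(blood_tissue, brain_tissues)
  if (!all(tiss %in% consensus$tissue) && nrow(consensus) > 0)
    stop("consensus results missing tissue(s): ",
         paste(setdiff(tiss, consensus$tissue), collapse = ", "),
         call. = FALSE)
  wide <- function(df, col) {
    out <- stats::reshape(
      df[, c("snp_id", "probe_id", "tissue", col)],
      idvar = c("snp_id", "probe_id"), timevar = "tissue",
      direction = "wide")
    names(out) <- sub(paste0("^", col, "\\."), paste0(col, "_"), names(out))
    out
  }
  calls <- NULL
  if (nrow(consensus)) {
    qw <- wide(consensus, "q")
    bw <- wide(consensus, "beta")
    qb <- qw[[paste0("q_", blood_tissue)]]
    qbr <- as.matrix(qw[paste0("q_", brain_tissues)])
    sig_b <- !is.na(qb) & qb < q_thresh
    sig_br <- !is.na(qbr) & qbr < q_thresh
    n_br_sig <- rowSums(sig_br)
    brain_ok <- if (strict_shared) n_br_sig == length(brain_tissues)
                else n_br_sig >= 1
    call <- ifelse(sig_b & brain_ok, "shared_all",
            ifelse(sig_b & n_br_sig == 0, "blood_specific",
            ifelse(!sig_b & n_br_sig >= 1, "brain_specific", "null")))
    # blood-significant with partial brain support under strict mode:
    # counts as shared under the relaxed rule, blood_specific otherwise
    part <- sig_b & !brain_ok & n_br_sig >= 1
    call[part] <- if (strict_shared) "blood_specific" else "shared_all"
    calls <- cbind(qw[, c("snp_id", "probe_id")], call = call,
                   qw[, -(1:2), drop = FALSE], bw[, -(1:2), drop = FALSE])
  }
  if (!is.null(restricted) && nrow(restricted)) {
    tested <- restricted[restricted$status == "tested", , drop = FALSE]
    if (nrow(tested)) {
      key <- paste(tested$snp_id, tested$probe_id, sep = ":")
      for (k in unique(key)) {
        rows <- tested[key == k, , drop = FALSE]
        sig <- !is.na(rows$q) & rows$q < q_thresh
        if (!any(sig)) next
        in_blood <- any(rows$tissue[sig] == blood_tissue)
        rcall <- if (in_blood) "blood_restricted_expression"
                 else "brain_restricted_expression"
        rrow <- data.frame(snp_id = rows$snp_id[1],
                           probe_id = rows$probe_id[1], call = rcall,
                           stringsAsFactors = FALSE)
        calls <- merge_fill(calls, rrow)
      }
    }
  }
  if (is.null(calls))
    calls <- data.frame(snp_id = character(0), probe_id = character(0),
                        call = character(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

# row-bind data frames with differing columns, filling with NA
merge_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
  rbind(a, b[names(a)])
}

#' Direction-of-effect consistency across tissues
#'
#' A pair's effect direction is consistent iff all its per-tissue betas
#' share one sign; a zero beta counts as inconsistent and is flagged.
#'
#' @param betas Numeric matrix or data frame, one row per pair, one column
#'   per tissue.
#' @return List with `consistent` (logical per pair), `n_consistent`, and
#'   `zero_flag` (pairs with a zero beta).
#' @export
direction_consistency <- function(betas) {
  b <- as.matrix(betas)
  stopifnot(all(is.finite(b)))
  zero <- rowSums(b == 0) > 0
  cons <- (rowSums(b > 0) == ncol(b) | rowSums(b < 0) == ncol(b)) & !zero
  list(consistent = cons, n_consistent = sum(cons), zero_flag = zero)
}

#' Tissue-by-trait-class count table
#'
#' Tallies tested and significant associations per tissue per trait class,
#' with row percentages over classes. Each catalog record contributes once,
#' so a SNP linked to multiple traits is counted per record. Unassigned
#' trait classes are counted under "other" with a warning.
#'
#' @param results Long eQTL results (consensus or restricted) with
#'   `tissue`, `status`, `significant` and a `trait_class` column attached
#'   via the pair's GWAS record.
#' @return Data frame with `tissue`, `trait_class`, `n_tested`, `n_signif`,
#'   `pct_tested`, `pct_signif` (percentages within tissue rows).
#' @export
count_table <- function(results) {
  r <- results
  if (any(r$trait_class == "unassigned")) {
    warning("unassigned trait classes counted as 'other'", call. = FALSE)
    r$trait_class[r$trait_class == "unassigned"] <- "other"
  }
  classes <- c("blood", "brain", "other")
  tissues <- unique(r$tissue)
  out <- expand.grid(tissue = tissues, trait_class = classes,
                     stringsAsFactors = FALSE)
  out$n_tested <- mapply(function(tis, cl)
    sum(r$tissue == tis & r$trait_class == cl & r$status == "tested"),
    out$tissue, out$trait_class)
  out$n_signif <- mapply(function(tis, cl)
    sum(r$tissue == tis & r$trait_class == cl & r$significant),
    out$tissue, out$trait_class)
  for (tis in tissues) {
    sel <- out$tissue == tis
    tt <- sum(out$n_tested[sel]); ts <- sum(out$n_signif[sel])
    out$pct_tested[sel] <- if (tt > 0) 100 * out$n_tested[sel] / tt else 0
    out$pct_signif[sel] <- if (ts > 0) 100 * out$n_signif[sel] / ts else 0
  }
  out
}

#' Chi-squared and two-proportion z tests on count tables
#'
#' Pearson chi-squared (no continuity correction) on the supplied
#' contingency table, plus — for a 2 x 2 successes/totals comparison — the
#' two-sided two-proportion z-test with pooled variance. For such data the
#' chi-squared statistic equals z squared.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two proportions.
#' @return List with `z`, `p_z`, `chisq`, `df`, `p_chisq`, and `degenerate`
#'   (TRUE when a margin is zero, in which case p = 1).
#' @export
proportion_tests <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0 || (x1 + x2) == 0 || (x1 + x2) == (n1 + n2)) {
    return(list(z = 0, p_z = 1, chisq = 0, df = 1, p_chisq = 1,
                degenerate = TRUE))
  }
  p_pool <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  p_z <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(z = z, p_z = p_z, chisq = unname(ct$statistic),
       df = unname(ct$parameter), p_chisq = ct$p.value, degenerate = FALSE)
}
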