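#' Detection filter for expression probes
#'
#' A probe is kept iff it is detected (detection p-value below `p_thresh`)
#' in strictly more than `frac` of samples. With the defaults a probe
#' detected in exactly 95 of 100 samples is dropped; 96 of 100 is kept.
#'
#' @param detection_p Probe-by-sample matrix of detection p-values.
#' @param p_thresh Per-cell detection cut (strict `<`).
#' @param frac Required detected fraction (strict `>`).
#' @return Character vector of kept probe ids (rownames).
#' @export
detection_filter <- function(detection_p, p_thresh = 0.01, frac = 0.95) {
  det_frac <- rowMeans(detection_p < p_thresh)
  rownames(detection_p)[det_frac > frac]
}

#' Exclude probes with design problems or an analyzed SNP in the 50-mer
#'
#' A probe is excluded iff its quality flag is not "good" (ambiguous
#' multi-mapping or design problems), or any analyzed SNP falls inside its
#' 50-mer genomic interval. Probe intervals are 0-based half-open (BED);
#' SNP positions are 1-based points, so a SNP at 1-based position `s`
#' overlaps `[start, end)` iff `start < s <= end`.
#'
#' @param probes Data frame with `probe_id`, `chromosome`, `start`, `end`
#'   (0-based half-open, length 50) and `quality_flag`.
#' @param snps Data frame with `snp_id`, `chromosome`, `position` (1-based)
#'   for the SNPs carried into analysis.
#' @return List with `kept` (probe ids), `excluded` (data frame `probe_id`,
#'   `reason` in `{quality, snp_in_probe}`).
#' @export
probe_exclusions <- function(probes, snps) {
  if (any(probes$end - probes$start != 50))
    stop("malformed probe annotation: intervals must have length 50",
         call. = FALSE)
  reasons <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    pr <- probes[i, ]
    bad <- character(0)
    if (pr$quality_flag != "good") bad <- c(bad, "quality")
    hit <- snps$chromosome == pr$chromosome &
      snps$position > pr$start & snps$position <= pr$end
    if (any(hit)) bad <- c(bad, "snp_in_probe")
    reasons[[i]] <- bad
  }
  drop <- lengths(reasons) > 0
  list(kept = probes$probe_id[!drop],
       excluded = data.frame(probe_id = rep(probes$probe_id,
                                            lengths(reasons)),
                             reason = unlist(reasons),
                             stringsAsFactors = FALSE))
}

#' Percentile-rank expression profile per tissue
#'
#' For one tissue, probes failing the detection filter get rank 0; detected
#' probes are ranked by the chosen statistic (mean or variance of expression
#' across samples, ties averaged) and scaled so the highest-ranked detected
#' probe has rank 1.0. The rank denominator is the count of detected probes,
#' so undetected probes sit at 0 and the top detected probe at exactly 1,
#' making profiles comparable across tissues with different detected counts.
#'
#' @param expr Probe-by-sample expression matrix for one tissue.
#' @param detected Character vector of probes passing [detection_filter()]
#'   in this tissue.
#' @param statistic "mean" or "variance".
#' @return Named numeric vector of ranks in `[0, 1]`, one per probe row of
#'   `expr`.
#' @export
percentile_rank_profile <- function(expr, detected,
                                    statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  stat <- switch(statistic,
                 mean = rowMeans(expr),
                 variance = apply(expr, 1, stats::var))
  out <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  det <- rownames(expr) %in% detected
  if (any(det)) {
    r <- rank(stat[det], ties.method = "average")
    out[det] <- r / max(r)
  }
  out
}

#' Cross-tissue rank-profile comparison table
#'
#' Convenience wrapper building the mean- and variance-rank profiles for
#' several tissues into one long table for plotting or export.
#'
#' @param expr_list Named list of probe-by-sample matrices, one per tissue.
#' @param detected_list Named list of detected-probe vectors (same names).
#' @return Data frame `probe_id`, `tissue`, `mean_rank`, `var_rank`.
#' @export
rank_profile_table <- function(expr_list, detected_list) {
  stopifnot(identical(names(expr_list), names(detected_list)))
  do.call(rbind, lapply(names(expr_list), function(tis) {
    mr <- percentile_rank_profile(expr_list[[tis]], detected_list[[tis]],
                                  "mean")
    vr <- percentile_rank_profile(expr_list[[tis]], detected_list[[tis]],
                                  "variance")
    data.frame(probe_id = names(mr), tissue = tis, mean_rank = unname(mr),
               var_rank = unname(vr), stringsAsFactors = FALSE)
  }))
}
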