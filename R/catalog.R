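#' Filter GWAS-catalog records by the study inclusion criteria
#'
#' A record is kept iff all six criteria hold: discovery p-value < 5e-8;
#' initial sample size > 1000 (or > 1000 cases for binomial traits);
#' replication sample size > 500 (or > 500 cases); number of SNPs in the
#' study > 100,000; European ancestry; and risk allele frequency >= 0.01.
#' All comparisons are strict except the risk-allele-frequency floor, which
#' is inclusive. The ancestry match is a case-insensitive substring test for
#' "European", since the catalog's ancestry field is free text. Records with
#' missing required fields are dropped with reason "malformed".
#'
#' Filtering is a pure per-record predicate, so it is idempotent and
#' independent of record order. Duplicate SNP ids across studies are kept as
#' separate records; use [unique()] on `kept$snp_id` for a distinct-SNP view.
#'
#' @param records Data frame with columns `snp_id`, `trait`, `discovery_p`,
#'   `initial_n`, `replication_n`, `n_snps_in_study`, `ancestry`,
#'   `risk_allele_freq`, and optionally `is_binomial` (case counts stand in
#'   for sample sizes when TRUE).
#' @param p_max,initial_n_min,replication_n_min,n_snps_min,raf_min
#'   Thresholds; defaults are the standard criteria.
#' @return List with `kept`, `dropped` (data frames) and `reasons`
#'   (`snp_id`, `trait`, `reason` with reasons in
#'   `{p, initial_n, replication_n, n_snps, ancestry, raf, malformed}`).
#' @export
filter_catalog <- function(records, p_max = 5e-8, initial_n_min = 1000,
                           replication_n_min = 500, n_snps_min = 100000,
                           raf_min = 0.01) {
  req <- c("snp_id", "discovery_p", "initial_n", "replication_n",
           "n_snps_in_study", "ancestry", "risk_allele_freq")
  if (!all(req %in% names(records)))
    stop("records must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    bad <- character(0)
    vals <- c(r$discovery_p, r$initial_n, r$replication_n,
              r$n_snps_in_study, r$risk_allele_freq)
    if (anyNA(vals) || is.na(r$ancestry)) {
      bad <- "malformed"
    } else {
      if (!(r$discovery_p < p_max)) bad <- c(bad, "p")
      if (!(r$initial_n > initial_n_min)) bad <- c(bad, "initial_n")
      if (!(r$replication_n > replication_n_min))
        bad <- c(bad, "replication_n")
      if (!(r$n_snps_in_study > n_snps_min)) bad <- c(bad, "n_snps")
      if (!grepl("european", r$ancestry, ignore.case = TRUE))
        bad <- c(bad, "ancestry")
      if (!(r$risk_allele_freq >= raf_min)) bad <- c(bad, "raf")
    }
    reasons[[i]] <- bad
  }
  drop <- lengths(reasons) > 0
  trait <- if ("trait" %in% names(records)) records$trait else NA_character_
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE],
       reasons = data.frame(snp_id = rep(records$snp_id, lengths(reasons)),
                            trait = rep(trait, lengths(reasons)),
                            reason = unlist(reasons),
                            stringsAsFactors = FALSE))
}

#' Attach blood/brain/other trait classes from a curated mapping
#'
#' Trait classification is a manual curation step, supplied as a mapping
#' from exact trait strings to classes; it is looked up, never computed.
#' Traits absent from the mapping get class "unassigned" with a warning.
#'
#' @param records Catalog data frame with a `trait` column.
#' @param mapping Either a named character vector (`trait -> class`) or a
#'   data frame with columns `trait` and `trait_class`.
#' @return `records` with a `trait_class` column added/overwritten.
#' @export
annotate_traits <- function(records, mapping) {
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.character(mapping$trait_class), mapping$trait)
  } else {
    map <- mapping
  }
  cls <- unname(map[records$trait])
  miss <- is.na(cls)
  if (any(miss))
    warning(sum(miss), " trait(s) not in mapping; set to 'unassigned'",
            call. = FALSE)
  cls[miss] <- "unassigned"
  records$trait_class <- cls
  records
}
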