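#' Write a dosage matrix as a minimal VCF with a DS FORMAT field
#'
#' One record per SNP with GT set from rounded dosages and DS carrying the
#' continuous dosage (expected minor-allele count). The minor allele is
#' written as ALT.
#'
#' @param dosage Sample-by-SNP dosage matrix.
#' @param snps SNP annotation data frame (`snp_id`, `chromosome`,
#'   `position`, `minor_allele`, `major_allele`).
#' @param path Output file path (plain text, `.vcf`).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(dosage, snps, path) {
  ids <- rownames(dosage)
  g <- hard_genotypes(dosage)
  gt_str <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Estimated alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(ncol(dosage))) {
    fields <- paste0(gt_str[g[, j] + 1L], ":",
                     formatC(dosage[, j], digits = 3, format = "f"))
    writeLines(paste(c(snps$chromosome[j], snps$position[j], snps$snp_id[j],
                       snps$major_allele[j], snps$minor_allele[j], ".",
                       "PASS", ".", "GT:DS", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dosage matrix from a VCF with DS (or GT) genotypes
#'
#' Parses the VCF with `vcfR` and extracts the per-sample DS field as a
#' numeric sample-by-SNP matrix; when DS is absent, falls back to counting
#' ALT alleles in GT.
#'
#' @param path VCF file path.
#' @return List with `dosage` (sample-by-SNP matrix) and `snps` (annotation
#'   data frame).
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(x)
      sum(as.integer(strsplit(x, "[/|]")[[1]])), numeric(1)),
      nrow = nrow(gt), dimnames = dimnames(gt))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = fix$ID, chromosome = fix$CHROM,
                     position = as.numeric(fix$POS),
                     major_allele = fix$REF, minor_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  dosage <- t(ds)
  rownames(dosage) <- colnames(v@gt)[-1]
  colnames(dosage) <- snps$snp_id
  list(dosage = dosage, snps = snps)
}

#' Write a probe annotation BED file
#'
#' Standard BED3+ with 0-based half-open intervals: chromosome, start, end,
#' probe id, quality flag.
#'
#' @param probes Probe annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(probes, path) {
  utils::write.table(
    probes[, c("chromosome", "start", "end", "probe_id", "quality_flag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe annotation BED file
#' @param path BED path written by [write_probe_bed()].
#' @return Probe annotation data frame.
#' @export
read_probe_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chromosome", "start", "end", "probe_id",
                  "quality_flag")[seq_len(ncol(bed))]
  bed$chromosome <- as.character(bed$chromosome)
  bed
}

#' Write a numeric matrix as TSV with row names in the first column
#' @param x Matrix.
#' @param path Output path.
#' @param id_col Name for the rowname column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
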