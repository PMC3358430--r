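# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact HWE p-value by direct enumeration over heterozygote counts, using
# plain factorial arithmetic (independent of the lgamma-based implementation).
hwe_brute_force <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  if (n_a > n) n_a <- 2 * n - n_a
  hets <- seq(n_a %% 2, n_a, by = 2)
  w <- vapply(hets, function(h) {
    hr <- (n_a - h) / 2
    hc <- n - h - hr
    2^h * exp(lfactorial(n) - lfactorial(hc) - lfactorial(h) -
                lfactorial(hr))
  }, numeric(1))
  w <- w / sum(w)
  obs <- w[hets == n_Aa]
  sum(w[w <= obs * (1 + 1e-12)])
}

# OLS dose coefficient/SE by explicit normal equations.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = as.numeric(beta), se = as.numeric(se), df = df)
}

# Hand step-up BH adjustment.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# A deterministic QC fixture with planted filter violations and known
# reason codes for every record.
qc_fixture <- function() {
  snps <- data.frame(
    snp_id = paste0("fx", 1:6),
    chromosome = "1",
    position = (1:6) * 1e6,
    call_rate = c(0.96, 0.90, 0.99, 0.99, 0.99, 0.99),
    maf = c(0.05, 0.20, 0.009, 0.30, 0.05, 0.20),
    hwe_p = c(0.5, 0.5, 0.5, 5e-8, 0.5, 0.5),
    imputed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    imputation_rsq = c(NA, NA, NA, NA, 0.29, 0.95),
    stringsAsFactors = FALSE
  )
  truth <- list(fx1 = character(0), fx2 = "callrate", fx3 = "maf",
                fx4 = "hwe", fx5 = "rsq", fx6 = character(0))
  probes <- data.frame(
    chromosome = "1",
    start = c(100L, 100L, 200L, 5000L),
    end = c(150L, 150L, 250L, 5050L),
    probe_id = paste0("pb", 1:4),
    quality_flag = c("good", "good", "ambiguous", "good"),
    stringsAsFactors = FALSE
  )
  probe_snps <- data.frame(snp_id = c("s1", "s2"), chromosome = "1",
                           position = c(101L, 100L),
                           stringsAsFactors = FALSE)
  probe_truth <- list(pb1 = "snp_in_probe", pb2 = "snp_in_probe",
                      pb3 = "quality", pb4 = character(0))
  # pb1/pb2 share the interval [100,150): SNP at 101 overlaps, 100 does not,
  # so both probes are excluded only through the 101 SNP
  list(snps = snps, snp_truth = truth, probes = probes,
       probe_snps = probe_snps, probe_truth = probe_truth)
}
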