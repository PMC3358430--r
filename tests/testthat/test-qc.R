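test_that("HWE exact test matches hand-enumerated small cases", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
})

test_that("HWE exact test agrees with brute-force enumeration, total <= 50", {
  for (n in c(2, 5, 17, 50)) {
    for (n_aa in 0:min(n, 12)) {
      for (n_Aa in 0:(n - n_aa)) {
        n_AA <- n - n_aa - n_Aa
        expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                     hwe_brute_force(n_AA, n_Aa, n_aa),
                     tolerance = 1e-12,
                     label = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
      }
    }
  }
})

test_that("SNP filter applies the call-rate/MAF/HWE/rsq thresholds", {
  fx <- qc_fixture()
  res <- filter_snps(fx$snps)
  expect_setequal(res$kept$snp_id, c("fx1", "fx6"))
  for (id in names(fx$snp_truth)) {
    expect_setequal(res$reasons$reason[res$reasons$snp_id == id],
                    fx$snp_truth[[id]])
  }
  # boundary: exactly at threshold is kept (strict <)
  ok <- data.frame(snp_id = "b1", call_rate = 0.95, maf = 0.01,
                   hwe_p = 1e-7, imputed = TRUE, imputation_rsq = 0.3)
  expect_equal(filter_snps(ok)$kept$snp_id, "b1")
})

test_that("SNP filter is idempotent, order-independent, NA-safe", {
  fx <- qc_fixture()
  once <- filter_snps(fx$snps)
  twice <- filter_snps(once$kept)
  expect_identical(once$kept$snp_id, twice$kept$snp_id)
  shuffled <- filter_snps(fx$snps[c(4, 2, 6, 1, 3, 5), ])
  expect_setequal(shuffled$kept$snp_id, once$kept$snp_id)
  bad <- fx$snps
  bad$maf[1] <- NA
  res <- filter_snps(bad)
  expect_equal(res$reasons$reason[res$reasons$snp_id == "fx1"], "malformed")
})

test_that("LD pruning keeps one of an identical pair and the first by position", {
  set.seed(1)
  base <- rnorm(100)
  dos <- cbind(a = base, b = base, c = rnorm(100))
  res <- ld_prune(dos)
  expect_setequal(res$kept, c("a", "c"))
})

test_that("LD pruning keeps independent SNPs and respects the window schedule", {
  set.seed(2)
  g <- simulate_genotypes(cohort_spec(1000, 200, maf_range = c(0.2, 0.5),
                                      seed = 2))
  res <- ld_prune(g$dosage)
  expect_gt(length(res$kept) / 200, 0.95)

  # 55 SNPs: SNPs 51-55 are copies of SNP 1 but never share a window with
  # it under (window 50, step 5): windows are 1-50, 6-55
  set.seed(3)
  x1 <- rnorm(50)
  m <- sapply(1:55, function(j) if (j >= 51) x1 else if (j == 1) x1
              else rnorm(50))
  colnames(m) <- paste0("s", 1:55)
  res2 <- ld_prune(m)
  expect_true("s1" %in% res2$kept)
  # copies of s1 do co-occur with each other in window 6-55: one survives
  expect_equal(sum(paste0("s", 51:55) %in% res2$kept), 1)
})

test_that("no surviving within-window pair exceeds the r2 threshold", {
  set.seed(4)
  n <- 150
  block <- rnorm(n)
  dos <- sapply(1:30, function(j)
    if (j %% 3 == 0) block + rnorm(n, sd = 0.3) else rnorm(n))
  colnames(dos) <- paste0("s", 1:30)
  res <- ld_prune(dos, window_snps = 30, step_snps = 5)
  kept <- res$kept
  r2 <- cor(dos[, kept])^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.2 + 1e-12)
})

test_that("zero-variance SNPs are kept and flagged", {
  dos <- cbind(a = rnorm(50), z = rep(1, 50))
  res <- ld_prune(dos)
  expect_true("z" %in% res$kept)
  expect_equal(res$zero_variance, "z")
})

test_that("IBS distance is zero for identical samples and MDS flags outliers", {
  g <- simulate_genotypes(cohort_spec(100, 600, maf_range = c(0.2, 0.5),
                                      seed = 12, n_outlier_samples = 2,
                                      outlier_shift = 0.3))
  d <- ibs_distance(g$genotype)
  expect_equal(d[1, 1], 0)
  expect_true(isSymmetric(d))

  mds <- ibs_mds(g$dosage)
  expect_true(all(g$outlier_samples %in% which(mds$outliers)))
  expect_lte(sum(mds$outliers), length(g$outlier_samples) + 2)
  expect_gte(stats::var(mds$components[, 1]),
             stats::var(mds$components[, 2]))
})

test_that("identical samples sit at IBS distance zero", {
  g <- simulate_genotypes(cohort_spec(20, 100, seed = 13,
                                      n_duplicate_pairs = 1))
  d <- ibs_distance(g$genotype)
  dp <- g$duplicate_pairs
  expect_equal(d[dp[1, 1], dp[1, 2]], 0)
})

test_that("MDS separates a planted two-population mixture on C1", {
  g <- simulate_genotypes(cohort_spec(100, 1000, maf_range = c(0.2, 0.4),
                                      seed = 14, n_outlier_samples = 50,
                                      outlier_shift = 0.2))
  mds <- ibs_mds(g$dosage, sd_threshold = 1e6)
  lab <- seq_len(100) %in% g$outlier_samples
  c1 <- mds$components[, 1]
  # silhouette on the 1-d embedding
  sil <- vapply(seq_len(100), function(i) {
    a <- mean(abs(c1[i] - c1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    b <- mean(abs(c1[i] - c1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("degenerate all-identical genotype matrix yields zero components", {
  dos <- matrix(1, nrow = 5, ncol = 10,
                dimnames = list(paste0("s", 1:5), paste0("m", 1:10)))
  mds <- ibs_mds(dos)
  expect_true(all(mds$components == 0))
  expect_false(any(mds$outliers))
})

test_that("duplicate pairs estimate pihat 1 and one member is excluded", {
  g <- simulate_genotypes(cohort_spec(30, 5000, maf_range = c(0.2, 0.5),
                                      seed = 15, n_duplicate_pairs = 1))
  rel <- relatedness_exclude(g$dosage)
  dp <- g$duplicate_pairs
  ids <- g$sample_ids[dp[1, ]]
  row <- rel$pairs[rel$pairs$id1 == ids[1] & rel$pairs$id2 == ids[2], ]
  expect_equal(row$pihat, 1)
  expect_equal(row$ibs_distance, 0)
  # one member excluded, the later id on a call-rate tie
  expect_equal(rel$excluded, max(ids))
})

test_that("unrelated samples estimate near-zero pihat at many markers", {
  g <- simulate_genotypes(cohort_spec(6, 10000, maf_range = c(0.2, 0.5),
                                      seed = 16))
  rel <- relatedness_exclude(g$dosage)
  expect_true(all(rel$pairs$pihat < 0.05))
  expect_equal(rel$excluded, character(0))
})

test_that("the pihat exclusion threshold is strict", {
  g <- simulate_genotypes(cohort_spec(10, 500, seed = 17,
                                      n_duplicate_pairs = 1))
  # a duplicate pair has pihat exactly 1; with threshold 1 it is retained
  rel <- relatedness_exclude(g$dosage, threshold = 1)
  expect_equal(rel$excluded, character(0))
})

test_that("the lower-call-rate member of a related pair is excluded", {
  g <- simulate_genotypes(cohort_spec(10, 3000, maf_range = c(0.2, 0.5),
                                      seed = 18, n_duplicate_pairs = 1))
  dp <- g$duplicate_pairs
  cr <- rep(1, 10)
  cr[dp[1, 1]] <- 0.9   # first member has the worse call rate
  rel <- relatedness_exclude(g$dosage, call_rates = cr)
  expect_equal(rel$excluded, g$sample_ids[dp[1, 1]])
})
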