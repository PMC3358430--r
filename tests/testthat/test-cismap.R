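test_that("cis pairing applies the 500 kb window and chromosome gate", {
  snps <- data.frame(snp_id = c("s1", "s2", "s3"),
                     chromosome = c("1", "1", "chr1"),
                     position = c(1e6, 1e6, 1e6))
  probes <- data.frame(probe_id = c("pA", "pB", "pC"),
                       chromosome = c("1", "1", "2"),
                       start = c(1499974, 1499976, 999975),
                       end = c(1500024, 1500026, 1000025))
  # midpoints: pA 1,499,999 (in), pB 1,500,001 (out), pC on chr2
  pairs <- pair_cis(snps, probes)
  expect_true(all(c("pA") %in% pairs$probe_id))
  expect_false("pB" %in% pairs$probe_id)
  expect_false("pC" %in% pairs$probe_id)
  # "chr1" and "1" dialects are the same chromosome
  expect_equal(sum(pairs$snp_id == "s3"), 1)
  expect_equal(pairs$distance[pairs$snp_id == "s1" &
                              pairs$probe_id == "pA"], 499999)
})

test_that("minor-homozygote filter requires at least 3 homozygotes", {
  dose2 <- c(rep(0, 45), rep(1, 3), 2, 2)
  dose3 <- c(rep(0, 44), rep(1, 3), 2, 2, 2)
  expect_false(min_homozygote_filter(dose2))
  expect_true(min_homozygote_filter(dose3))
  # dosages are rounded: 1.6 counts as a homozygote
  expect_true(min_homozygote_filter(c(rep(0, 10), 1.6, 1.5, 1.9)))
  # MAF 0.2 at n = 500 passes essentially surely (expected 20 homozygotes)
  set.seed(7)
  expect_true(min_homozygote_filter(rbinom(500, 2, 0.2)))
})

test_that("dosage regression recovers the hand-computed slope", {
  f <- fit_eqtl(c(1, 2, 2), c(0, 1, 2))
  expect_equal(f$beta, 0.5)
  expect_equal(f$status, "tested")
})

test_that("regression matches the normal-equations oracle on random designs", {
  set.seed(11)
  for (rep in 1:300) {
    n <- sample(8:20, 1)
    k <- sample(0:4, 1)
    dose <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (length(unique(dose)) == 1) next
    C <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    y <- rnorm(n)
    f <- if (is.null(C)) fit_eqtl(y, dose) else fit_eqtl(y, dose, C)
    X <- cbind(1, dose, C)
    if (qr(X)$rank < ncol(X)) next
    o <- ols_oracle(y, X)
    expect_lt(abs(f$beta - o$beta[2]), 1e-8)
    expect_lt(abs(f$se - o$se[2]), 1e-8)
    expect_equal(f$df, o$df)
    expect_equal(f$p, 2 * pt(abs(o$beta[2] / o$se[2]), o$df,
                             lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("null regressions give uniform p at the nominal type-I rate", {
  set.seed(12)
  n <- 40
  dose <- rbinom(n, 2, 0.3)
  reps <- 4000
  p <- vapply(seq_len(reps), function(i) fit_eqtl(rnorm(n), dose)$p,
              numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("covariates orthogonal to dose leave the slope unchanged", {
  set.seed(13)
  n <- 60
  dose <- rbinom(n, 2, 0.4)
  y <- 0.4 * dose + rnorm(n)
  raw <- fit_eqtl(y, dose)
  z <- unname(resid(lm(rnorm(n) ~ dose)))  # orthogonal to intercept + dose
  adj <- fit_eqtl(y, dose, cbind(z = z))
  expect_lt(abs(raw$beta - adj$beta), 1e-10)
})

test_that("collinear or constant designs are flagged, not errors", {
  y <- rnorm(20)
  f <- fit_eqtl(y, rep(1, 20))
  expect_equal(f$status, "collinear")
  expect_true(is.na(f$p))
  dose <- rbinom(20, 2, 0.4)
  f2 <- fit_eqtl(y, dose, cbind(copy = dose))
  expect_equal(f2$status, "collinear")
})

test_that("BH adjustment matches hand-computed step-up values", {
  r <- bh_fdr(c(0.01, 0.03, 0.04))
  expect_equal(r$q, c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.2)$q, 0.2)
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  expect_equal(bh_fdr(numeric(0))$q, numeric(0))
  set.seed(14)
  p <- runif(50)
  expect_equal(bh_fdr(p)$q, bh_oracle(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("conditioning on the causal proxy absorbs the signal", {
  set.seed(15)
  n <- 200
  worse <- 0L
  reps <- 60
  for (r in 1:reps) {
    proxy <- rbinom(n, 2, 0.3)
    # dose in LD with proxy at r2 ~ 0.8 via allele-level resampling
    dose <- proxy
    flip <- runif(n) < 0.12
    dose[flip] <- rbinom(sum(flip), 2, 0.3)
    y <- 0.6 * proxy + rnorm(n)
    cf <- conditional_fit(y, dose, proxy)
    if (cf$conditional$p > cf$marginal$p) worse <- worse + 1L
  }
  expect_gte(worse / reps, 0.95)
})

test_that("an irrelevant proxy leaves the dose effect unchanged", {
  set.seed(16)
  n <- 300
  dose <- rbinom(n, 2, 0.3)
  proxy <- rbinom(n, 2, 0.3)
  y <- 0.5 * dose + rnorm(n)
  cf <- conditional_fit(y, dose, proxy)
  expect_lt(abs(cf$conditional$beta - cf$marginal$beta),
            2 * cf$marginal$se)
  expect_equal(cf$conditional$status, "tested")
  # proxy identical to dose is collinear
  cf2 <- conditional_fit(y, dose, dose)
  expect_equal(cf2$conditional$status, "collinear")
  expect_equal(cf2$marginal$status, "tested")
})

test_that("consensus extraction inner-joins tested pairs across tissues", {
  base <- data.frame(snp_id = c("s1", "s2", "s3"),
                     probe_id = c("p1", "p2", "p3"),
                     tissue = "blood", n_used = 100,
                     beta = 0.1, se = 0.1, t_stat = 1, p = c(0.01, 0.5, 0.9),
                     q = NA_real_, significant = FALSE,
                     status = "tested", distance = 1000)
  blood <- base
  fc <- base; fc$tissue <- "frontal_cortex"
  cb <- base; cb$tissue <- "cerebellum"
  cb$status[2] <- "excluded_undetected"   # p2 undetected in cerebellum
  cons <- consensus_set(list(blood = blood, frontal_cortex = fc,
                             cerebellum = cb))
  expect_setequal(unique(cons$consensus$probe_id), c("p1", "p3"))
  expect_setequal(unique(cons$restricted$probe_id), "p2")
  expect_equal(unique(cons$restricted$tested_in), "blood,frontal_cortex")

  # empty overlap: non-empty complements
  fc2 <- fc; fc2$status <- "excluded_min_hom"
  cons2 <- consensus_set(list(blood = blood, frontal_cortex = fc2))
  expect_equal(nrow(cons2$consensus), 0)
  expect_equal(sort(unique(cons2$restricted$snp_id)), c("s1", "s2", "s3"))
})

test_that("per-tissue mapping is invariant to sample and SNP order", {
  s <- cohort_spec(80, 6, maf_range = c(0.3, 0.5), seed = 17)
  co <- simulate_cohort(s, effects = list(
    planted_effect("@snp2", "@probe2", eqtl_tissues(), 1)),
    tissues = "blood")
  geno <- co$genotypes
  pairs <- pair_cis(geno$snps, co$probes)
  det <- co$probes$probe_id
  r1 <- map_tissue_eqtls(pairs, geno$dosage, co$expression$blood$expr,
                         co$covariates, det, "blood")
  perm <- sample(nrow(geno$dosage))
  r2 <- map_tissue_eqtls(pairs[rev(seq_len(nrow(pairs))), ],
                         geno$dosage[perm, ],
                         co$expression$blood$expr[, perm],
                         co$covariates[perm, ], det, "blood")
  m1 <- r1[order(r1$snp_id, r1$probe_id), ]
  m2 <- r2[order(r2$snp_id, r2$probe_id), ]
  expect_equal(m1$beta, m2$beta, tolerance = 1e-10)
  expect_equal(m1$q, m2$q, tolerance = 1e-10)
})

test_that("detection rate of a strong planted effect matches analytic power", {
  # one planted pair among nulls; BH with one strong signal admits the
  # planted pair at an effective level between alpha/m and alpha
  set.seed(18)
  n <- 501
  m_pairs <- 40
  hits <- 0L
  reps <- 40
  for (r in 1:reps) {
    dose <- matrix(rbinom(n * m_pairs, 2, 0.2), n)
    y <- matrix(rnorm(n * m_pairs), m_pairs, n)
    y[1, ] <- y[1, ] + 0.5 * dose[, 1]
    p <- vapply(1:m_pairs, function(j)
      fit_eqtl(y[j, ], dose[, j])$p, numeric(1))
    hits <- hits + bh_fdr(p)$significant[1]
  }
  pow <- analytic_power(power_spec(n, 0.2, 0.5, alpha = 0.05 / m_pairs,
                                   variance_convention =
                                     "residual_variance_1"))
  expect_lt(abs(hits / reps - pow), 0.03 + 3 * sqrt(pow * (1 - pow) / reps))
})
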