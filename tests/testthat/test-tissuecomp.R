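consensus_from_q <- function(q_blood, q_cb, q_fc, betas = c(1, 1, 1)) {
  data.frame(snp_id = "s1", probe_id = "p1",
             tissue = c("blood", "cerebellum", "frontal_cortex"),
             n_used = 400, beta = betas, se = 0.1, t_stat = 1,
             p = pmin(c(q_blood, q_cb, q_fc), 1),
             q = c(q_blood, q_cb, q_fc),
             significant = c(q_blood, q_cb, q_fc) < 0.05,
             status = "tested", distance = 1000,
             stringsAsFactors = FALSE)
}

test_that("sharing calls reproduce the canonical q-value patterns", {
  # strongly significant everywhere -> shared across all three tissues
  shared <- classify_sharing(consensus_from_q(9.46e-67, 6.72e-51, 1.45e-38))
  expect_equal(shared$call, "shared_all")
  # blood-driven signal absent from both brain regions
  blood <- classify_sharing(consensus_from_q(6.41e-32, 0.924, 0.896))
  expect_equal(blood$call, "blood_specific")
  # brain-driven signal absent from blood
  brain <- classify_sharing(consensus_from_q(0.89, 6.09e-5, 1.53e-8))
  expect_equal(brain$call, "brain_specific")
  # nothing significant
  expect_equal(classify_sharing(consensus_from_q(0.5, 0.7, 0.9))$call,
               "null")
})

test_that("strict versus relaxed shared calls differ on partial brain support", {
  partial <- consensus_from_q(1e-10, 1e-6, 0.5)
  expect_equal(classify_sharing(partial, strict_shared = TRUE)$call,
               "blood_specific")
  expect_equal(classify_sharing(partial, strict_shared = FALSE)$call,
               "shared_all")
})

test_that("restricted-expression pairs are called by detecting tissue", {
  restricted <- data.frame(
    snp_id = c("s9", "s9"), probe_id = c("p9", "p9"),
    tissue = c("cerebellum", "frontal_cortex"),
    n_used = 300, beta = 0.5, se = 0.1, t_stat = 5,
    p = c(1e-6, 1e-4), q = c(1e-5, 1e-3),
    significant = TRUE, status = "tested", distance = 0,
    tested_in = "cerebellum,frontal_cortex",
    stringsAsFactors = FALSE)
  calls <- classify_sharing(consensus_from_q(0.5, 0.6, 0.7), restricted)
  expect_true("brain_restricted_expression" %in% calls$call)
  restricted$tissue <- c("blood", "blood")
  calls2 <- classify_sharing(consensus_from_q(0.5, 0.6, 0.7), restricted)
  expect_true("blood_restricted_expression" %in% calls2$call)
})

test_that("relabeling blood and brain tissues permutes the calls", {
  df <- consensus_from_q(1e-8, 0.5, 0.6)
  fwd <- classify_sharing(df)
  swapped <- classify_sharing(df, blood_tissue = "cerebellum",
                              brain_tissues = c("blood", "frontal_cortex"))
  expect_equal(fwd$call, "blood_specific")
  expect_equal(swapped$call, "brain_specific")
})

test_that("direction consistency needs one shared sign across tissues", {
  b <- rbind(c(0.5, 0.3, 0.4), c(0.5, -0.3, 0.4), c(-1, -2, -0.1),
             c(0, 0.5, 0.5))
  d <- direction_consistency(b)
  expect_equal(d$consistent, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(d$n_consistent, 2)
  expect_equal(d$zero_flag, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("planted same-sign effects are seen as consistent when significant", {
  set.seed(41)
  n <- 500
  consist <- 0L; sig_all <- 0L
  for (r in 1:30) {
    dose <- rbinom(n, 2, 0.3)
    betas <- vapply(1:3, function(t) {
      f <- fit_eqtl(0.5 * dose + rnorm(n), dose)
      c(f$beta, f$p)
    }, numeric(2))
    if (all(betas[2, ] < 1e-4)) {
      sig_all <- sig_all + 1L
      if (direction_consistency(matrix(betas[1, ], nrow = 1))$consistent)
        consist <- consist + 1L
    }
  }
  expect_gte(consist / sig_all, 0.95)
})

test_that("count tables tally planted classes with row percentages", {
  res <- data.frame(
    tissue = rep(c("blood", "cerebellum"), each = 4),
    status = "tested",
    significant = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    trait_class = rep(c("blood", "brain", "other", "other"), 2),
    stringsAsFactors = FALSE)
  tab <- count_table(res)
  expect_equal(tab$n_tested[tab$tissue == "blood" &
                            tab$trait_class == "other"], 2)
  expect_equal(tab$n_signif[tab$tissue == "blood" &
                            tab$trait_class == "blood"], 1)
  for (tis in unique(tab$tissue))
    expect_equal(sum(tab$pct_tested[tab$tissue == tis]), 100,
                 tolerance = 0.1)
  # empty input: all-zero table
  empty <- count_table(res[0, ])
  expect_true(all(empty$n_tested == 0) || nrow(empty) == 0)
  # unassigned classes fold into "other" with a warning
  res$trait_class[1] <- "unassigned"
  expect_warning(tab2 <- count_table(res), "other")
  expect_equal(tab2$n_tested[tab2$tissue == "blood" &
                             tab2$trait_class == "other"], 3)
})

test_that("two-proportion z-test matches the pooled-variance hand formula", {
  r <- proportion_tests(10, 100, 20, 100)
  expect_equal(abs(r$z), 0.1 / sqrt(0.15 * 0.85 * 0.02), tolerance = 1e-10)
  expect_equal(r$p_z, 0.04767038, tolerance = 1e-6)
  # chi-squared on the same 2x2 equals z squared
  expect_equal(r$chisq, r$z^2, tolerance = 1e-10)
  # identical proportions: z = 0, p = 1
  same <- proportion_tests(5, 50, 5, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p_z, 1)
  # zero-margin tables are degenerate with p = 1
  degen <- proportion_tests(0, 50, 0, 60)
  expect_true(degen$degenerate)
  expect_equal(degen$p_z, 1)
})

test_that("sharing classification recovers a planted architecture", {
  set.seed(42)
  n <- 500
  arch <- c(shared_all = 4, blood_specific = 4, brain_specific = 4,
            null = 4)
  correct <- 0L; total <- 0L
  for (rep in 1:8) {
    rows <- list()
    for (kind in names(arch)) {
      for (i in seq_len(arch[[kind]])) {
        dose <- rbinom(n, 2, 0.2)
        eff <- switch(kind,
          shared_all = c(1, 1, 1), blood_specific = c(1, 0, 0),
          brain_specific = c(0, 1, 1), null = c(0, 0, 0))
        pr <- paste0(kind, i)
        for (t in 1:3) {
          f <- fit_eqtl(0.5 * eff[t] * dose + rnorm(n), dose)
          rows[[length(rows) + 1]] <- data.frame(
            snp_id = pr, probe_id = pr,
            tissue = c("blood", "cerebellum", "frontal_cortex")[t],
            n_used = n, beta = f$beta, se = f$se, t_stat = f$t_stat,
            p = f$p, q = NA_real_, significant = FALSE,
            status = "tested", distance = 0, truth = kind,
            stringsAsFactors = FALSE)
        }
      }
    }
    long <- do.call(rbind, rows)
    for (tis in unique(long$tissue)) {
      sel <- long$tissue == tis
      adj <- bh_fdr(long$p[sel])
      long$q[sel] <- adj$q
      long$significant[sel] <- adj$significant
    }
    calls <- classify_sharing(long)
    truth <- long$truth[match(paste(calls$snp_id, calls$probe_id),
                              paste(long$snp_id, long$probe_id))]
    correct <- correct + sum(calls$call == truth)
    total <- total + nrow(calls)
  }
  expect_gte(correct / total, 0.9)
})
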