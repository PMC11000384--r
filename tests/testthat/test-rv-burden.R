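qc_cohort <- function(gt, ab = NULL, gq = NULL, dp = NULL,
                      af_gnomad = 0.001) {
  n <- nrow(gt); v <- ncol(gt)
  dp <- dp %||% matrix(30, n, v)
  ab <- ab %||% ifelse(gt == 1L, 0.5, ifelse(gt == 2L, 0.98, 0.01))
  ab[is.na(ab)] <- 0.01
  ad_alt <- round(dp * ab); ad_ref <- dp - ad_alt
  gq <- gq %||% matrix(90, n, v)
  make_cohort(gt, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq, dp = dp,
              ann_overrides = list(af_gnomad = af_gnomad, af_1kg = af_gnomad))
}

test_that("per-call filters mask bad allele balance and low GQ", {
  gt <- matrix(c(1L, 1L, 2L, 0L), ncol = 1)
  gt <- cbind(gt, gt, gt)
  gt <- rbind(gt, matrix(0L, 36, 3))
  ab <- matrix(0.01, 40, 3)
  ab[1, 1] <- 0.15    # bad het AB -> masked
  ab[2, 1] <- 0.5
  ab[3, 1] <- 0.98
  ab[1, 2] <- 0.5; ab[2, 2] <- 0.5; ab[3, 2] <- 0.6   # bad hom AB
  ab[1, 3] <- 0.5; ab[2, 3] <- 0.5; ab[3, 3] <- 0.98
  gq <- matrix(90, 40, 3)
  gq[2, 3] <- 8       # low GQ -> masked
  co <- qc_cohort(gt, ab = ab, gq = gq)
  out <- qc_filter(co, qc_thresholds(af_max = 0.9))
  v <- co$variants$variant_id
  qgt <- out$cohort$gt
  # variant 1: the AB-0.15 het is gone (masked), the others remain
  expect_true(v[1] %in% colnames(qgt))
  expect_true(is.na(qgt[1, v[1]]))
  expect_equal(qgt[2, v[1]], 1L)
  # variant 2: hom call with AB 0.6 masked
  expect_true(is.na(qgt[3, v[2]]))
  # variant 3: the GQ-8 call masked
  expect_true(is.na(qgt[2, v[3]]))
})

test_that("per-variant filters drop by call rate, AF and allele counts", {
  n <- 100
  gt <- matrix(0L, n, 5)
  gt[1:5, 1] <- 1L                      # AC 5: passes
  gt[1, 2] <- 1L                        # singleton: dropped
  gt[1:2, 3] <- 1L                      # doubleton, good depth: kept
  gt[1:2, 4] <- 1L                      # doubleton, poor depth: dropped
  gt[1:5, 5] <- 1L                      # will fail call rate
  dp <- matrix(30, n, 5)
  dp[1:2, 4] <- 5
  co <- qc_cohort(gt, dp = dp)
  co$gt[6:17, 5] <- NA_integer_         # call rate 88/100 < 0.9
  out <- qc_filter(co, qc_thresholds(af_max = 0.05))
  v <- co$variants$variant_id
  kept <- colnames(out$cohort$gt)
  expect_true(v[1] %in% kept)
  expect_false(v[2] %in% kept)
  expect_true(v[3] %in% kept)
  expect_false(v[4] %in% kept)
  expect_false(v[5] %in% kept)
  rep <- out$report
  expect_equal(rep$fail_reason[rep$variant_id == v[2]], "singleton")
  expect_equal(rep$fail_reason[rep$variant_id == v[4]], "doubleton")
  expect_equal(rep$fail_reason[rep$variant_id == v[5]], "call_rate")
  # the literal alternative doubleton reading flips the decision
  out2 <- qc_filter(co, qc_thresholds(af_max = 0.05,
                                      doubleton_rule = "drop_high_depth"))
  kept2 <- colnames(out2$cohort$gt)
  expect_false(v[3] %in% kept2)
  expect_true(v[4] %in% kept2)
  # cohort-common and globally common variants are excluded
  gt6 <- matrix(0L, n, 1); gt6[1:30, 1] <- 1L
  co6 <- qc_cohort(gt6)
  expect_equal(qc_filter(co6)$report$fail_reason, "cohort_af")
  co7 <- qc_cohort(gt, af_gnomad = 0.05)
  rep7 <- qc_filter(co7)$report
  expect_true(all(!rep7$pass))
  expect_equal(rep7$fail_reason[rep7$variant_id == v[2]], "global_af")
})

test_that("tightening any QC threshold never enlarges the qualifying set", {
  set.seed(47)
  sim <- simulate_cohort(sim_config(seed = 47, n_subjects = 300,
                                    n_variants = 60, n_genes = 20,
                                    n_traits = 2, gq_mean = 40, gq_sd = 25))
  co <- sim$cohort
  base <- colnames(qc_filter(co)$cohort$gt)
  tighter <- list(
    qc_thresholds(gq_min = 30),
    qc_thresholds(call_rate_min = 0.98),
    qc_thresholds(het_ab_low = 0.35, het_ab_high = 0.65),
    qc_thresholds(af_max = 0.005),
    qc_thresholds(hwe_p_min = 0.01)
  )
  for (th in tighter) {
    expect_true(all(colnames(qc_filter(co, th)$cohort$gt) %in% base))
  }
})

test_that("the HWE conditional distribution matches independent oracles", {
  # minimal case (1 hom-ref, 0 het, 1 hom-alt): allele pairing gives
  # P(het = 2) = 2/3, P(het = 0) = 1/3, so p = 1/3
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_p(0, 2, 0), 1)
  # monomorphic: single outcome
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  # distribution sums to 1 and matches a random-pairing simulation
  d <- hwe_genotype_probs(10, 8)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  set.seed(8)
  sim <- oracle_hwe_sim(10, 8, reps = 40000)
  for (k in seq_len(nrow(d))) {
    expect_lt(abs(d$prob[k] - sim[[as.character(d$n_het[k])]]), 0.01)
  }
  # parity: only heterozygote counts of the minor-allele parity have mass
  expect_true(all(d$n_het %% 2 == 0))
  d2 <- hwe_genotype_probs(57 + 14 + 50, 14 + 2 * 50)
  expect_true(all(d2$n_het %% 2 == (14 + 100) %% 2))
  expect_equal(sum(d2$prob), 1, tolerance = 1e-10)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
})

test_that("gene collapsing sums genotypes and aggregates class counts", {
  gt <- rbind(
    c(1L, 1L, 0L),
    c(0L, 2L, 1L),
    c(NA, 0L, 0L)
  )
  co <- make_cohort(gt, genes = c("G1", "G1", "G2"))
  b <- collapse_gene(co, "G1")
  expect_equal(as.numeric(b), c(2, 2, 0))
  cc <- attr(b, "class_counts")
  expect_equal(unname(cc), c(2L, 2L, 1L))       # RR, RA, AA over both variants
  expect_equal(paste(cc, collapse = "|"), "2|2|1")
  expect_error(collapse_gene(co, "NOPE"), "no qualifying variants")
  # loop oracle on a random fixture
  set.seed(99)
  gt2 <- matrix(sample(c(0L, 1L, 2L, NA), 40 * 6, replace = TRUE),
                nrow = 40)
  co2 <- make_cohort(gt2, genes = rep(c("A", "B"), each = 3))
  b2 <- collapse_gene(co2, "A")
  for (i in 1:40) {
    s <- 0
    for (j in 1:3) if (!is.na(gt2[i, j])) s <- s + gt2[i, j]
    expect_equal(unname(b2[i]), s)
  }
})

test_that("burden regression recovers effects and matches closed-form OLS", {
  set.seed(13)
  n <- 5000
  b <- rbinom(n, 2, 0.02)
  covars <- data.frame(age = rnorm(n, 40, 10),
                       sex = rbinom(n, 1, 0.5),
                       PC1 = rnorm(n), PC2 = rnorm(n),
                       PC3 = rnorm(n), PC4 = rnorm(n))
  y <- 0.5 * b + 0.02 * covars$age + 0.3 * covars$sex + rnorm(n)
  res <- burden_regression(b, y, covars)
  expect_lt(abs(res$beta - 0.5), 3 * res$se)
  # normal-equations oracle
  X <- cbind(1, b, as.matrix(covars))
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$beta, beta_hat[2], tolerance = 1e-10)
  expect_equal(res$p_value,
               pchisq(res$chi_sq, 1, lower.tail = FALSE))
  # degenerate burden yields a null row
  res0 <- burden_regression(rep(0, n), y, covars)
  expect_true(is.na(res0$beta))
  # collinear covariates error with the offending column named
  covars$PC5 <- covars$PC1
  expect_error(burden_regression(b, y, covars), "collinear")
})

test_that("null regressions keep nominal type-I error", {
  set.seed(101)
  n <- 1500
  covars <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5),
                       PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
                       PC4 = rnorm(n))
  p <- replicate(400, {
    b <- rbinom(n, 1, 0.01)
    y <- 0.02 * covars$age + rnorm(n)
    burden_regression(b, y, covars)$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("the scan flags a strong spiked gene and is deterministic", {
  spike <- tibble::tibble(variant = 3, trait = "trait_01", effect = 1,
                          model = "additive")
  cfg <- sim_config(seed = 17, n_subjects = 4000, n_variants = 40,
                    n_genes = 12, n_traits = 3, effect_spikes = spike,
                    founder_spikes = tibble::tibble(variant = 3,
                                                    subpop = "GAR",
                                                    target_af = 0.02),
                    gt_missing_rate = 0)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  spiked_gene <- co$variants$gene[3]
  scan <- genome_wide_scan(co, thresholds = NULL,
                           p_threshold = 1e-4)
  res <- tidy(scan)
  top <- res[1, ]
  expect_equal(top$gene, spiked_gene)
  expect_equal(top$trait, "trait_01")
  expect_lt(top$p_value, 1e-4)
  # determinism: re-running the scan reproduces the table
  scan2 <- genome_wide_scan(co, thresholds = NULL, p_threshold = 1e-4)
  expect_identical(tidy(scan), tidy(scan2))
  g <- glance(scan)
  expect_equal(g$n_pairs, nrow(res))
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
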