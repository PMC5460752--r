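mk_est <- function(beta, se, n = 1000) {
  effect_estimate(beta, se, n, scale = "log_odds", term = "per_allele")
}

test_that("fixed-effect pooling follows the inverse-variance formulas", {
  # single study: identity
  e <- mk_est(0.25, 0.08)
  m1 <- fixed_effect_pool(list(e))
  expect_equal(m1$pooled$beta, 0.25)
  expect_equal(m1$pooled$se, 0.08)
  expect_true(is.na(m1$Q) && is.na(m1$i2))

  # equal weights: arithmetic mean, se / sqrt(2)
  m2 <- fixed_effect_pool(list(mk_est(0.1, 0.1), mk_est(0.3, 0.1)))
  expect_equal(m2$pooled$beta, 0.2, tolerance = 1e-12)
  expect_equal(m2$pooled$se, 0.1 / sqrt(2), tolerance = 1e-12)

  # contract errors
  bad <- effect_estimate(0.1, 0.1, 100, scale = "sd_activity",
                         term = "per_allele")
  expect_error(fixed_effect_pool(list(e, bad)), "common scale")
  expect_error(effect_estimate(0.1, -1, 10, "log_odds", "per_allele"),
               "non-negative")
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  set.seed(31)
  betas <- rnorm(5, 0.1, 0.2)
  ses <- runif(5, 0.05, 0.3)
  m <- fixed_effect_pool(lapply(1:5, function(i) mk_est(betas[i], ses[i])))
  ref <- metafor::rma(yi = betas, sei = ses, method = "FE")
  expect_equal(m$pooled$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$pooled$se, ref$se, tolerance = 1e-10)
  expect_equal(m$Q, ref$QE, tolerance = 1e-10)
  expect_equal(m$p_het, ref$QEp, tolerance = 1e-10)
  expect_equal(m$i2, max(0, (ref$QE - 4) / ref$QE) * 100, tolerance = 1e-10)
})

test_that("heterogeneity statistics match hand computation", {
  h0 <- heterogeneity(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(h0$Q, 0, tolerance = 1e-12)
  expect_equal(h0$i2, 0)
  # w = 4 each, pooled 0.5, Q = 4*0.25 + 4*0.25 = 2, I2 = 50%
  h <- heterogeneity(c(0, 1), c(0.5, 0.5))
  expect_equal(h$Q, 2, tolerance = 1e-12)
  expect_equal(h$df, 1L)
  expect_equal(h$i2, 50, tolerance = 1e-12)
  expect_equal(h$p_het, pchisq(2, 1, lower.tail = FALSE))
  expect_error(heterogeneity(0.5, 0.1), "fewer than 2")
})

test_that("pooling is permutation-invariant, bounded and associative", {
  set.seed(32)
  ests <- lapply(1:8, function(i) mk_est(rnorm(1, 0, 0.3),
                                         runif(1, 0.05, 0.4)))
  full <- fixed_effect_pool(ests)
  b <- vapply(ests, `[[`, 0, "beta")
  expect_gte(full$pooled$beta, min(b))
  expect_lte(full$pooled$beta, max(b))
  perm <- fixed_effect_pool(ests[sample(8)])
  expect_equal(perm$pooled$beta, full$pooled$beta, tolerance = 1e-12)

  # merging two pre-pooled halves equals pooling everything at once
  h1 <- fixed_effect_pool(ests[1:4])$pooled
  h2 <- fixed_effect_pool(ests[5:8])$pooled
  merged <- fixed_effect_pool(list(h1, h2))
  expect_equal(merged$pooled$beta, full$pooled$beta, tolerance = 1e-12)
  expect_equal(merged$pooled$se, full$pooled$se, tolerance = 1e-12)
})

test_that("homogeneous estimates give near-zero I2 and uniform heterogeneity p", {
  set.seed(33)
  i2s <- ps <- numeric(200)
  for (r in 1:200) {
    ses <- runif(5, 0.1, 0.3)
    betas <- rnorm(5, 0.2, ses) # common true effect, no heterogeneity
    h <- heterogeneity(betas, ses)
    i2s[r] <- h$i2
    ps[r] <- h$p_het
  }
  expect_lt(mean(i2s), 20) # truncation at 0 inflates the mean slightly
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("summary-table pooling adds POOLED rows with heterogeneity columns", {
  stats <- rbind(
    data.frame(study_id = "A", variant_id = "v", term = "per_allele",
               scale = "log_odds", beta = 0.1, se = 0.1, ci_lo = NA,
               ci_hi = NA, p = NA, n = 100L, n_case = 50L, n_ctrl = 50L,
               note = NA),
    data.frame(study_id = "B", variant_id = "v", term = "per_allele",
               scale = "log_odds", beta = 0.3, se = 0.1, ci_lo = NA,
               ci_hi = NA, p = NA, n = 100L, n_case = 50L, n_ctrl = 50L,
               note = NA))
  pooled <- pool_summary_stats(stats)
  expect_equal(pooled$study_id, "POOLED")
  expect_equal(pooled$beta, 0.2, tolerance = 1e-12)
  expect_equal(pooled$k, 2L)
  expect_true(all(c("Q", "i2", "p_het") %in% names(pooled)))
})
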