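test_that("standardization centres and scales against the reference group", {
  expect_equal(standardize_activity(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_activity(rnorm(100, 5, 2))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize_activity(rep(2, 10)), "distinct")
  # control-only reference ignores cases entirely
  vals <- c(10, 20, 1, 2, 3)
  status <- c(1L, 1L, 0L, 0L, 0L)
  expect_equal(standardize_activity(vals, "controls", status)[3:5],
               c(-1, 0, 1))
})

test_that("linear fit is exact on noiseless data and matches the normal equations", {
  g <- rep(0:2, each = 5)
  y <- 2 - 0.5 * g
  est <- fit_linear(y, g)
  expect_equal(est$beta, -0.5, tolerance = 1e-12)
  expect_equal(est$se, 0)
  expect_equal(est$p, 0)

  # oracle: explicit least-squares solution on a random 20 x 3 design
  set.seed(42)
  X <- cbind(1, rbinom(20, 2, 0.4), rnorm(20))
  y2 <- 0.3 - 0.8 * X[, 2] + 0.5 * X[, 3] + rnorm(20)
  beta_hat <- solve(crossprod(X), crossprod(X, y2))
  resid <- y2 - X %*% beta_hat
  s2 <- sum(resid^2) / (20 - 3)
  se_hat <- sqrt(diag(s2 * solve(crossprod(X))))
  est2 <- fit_linear(y2, X[, 2], covariates = data.frame(c1 = X[, 3]))
  expect_equal(est2$beta, beta_hat[2, 1], tolerance = 1e-10)
  expect_equal(est2$se, se_hat[2], tolerance = 1e-10)

  expect_error(fit_linear(y, rep(1, 15)), "constant")
})

test_that("an orthogonal covariate leaves the dose estimate unchanged", {
  set.seed(7)
  g <- rbinom(400, 2, 0.3)
  y <- 1 - 0.4 * g + rnorm(400, 0, 0.5)
  cov_raw <- rnorm(400)
  cov_orth <- resid(lm(cov_raw ~ g))
  e0 <- fit_linear(y, g)
  e1 <- fit_linear(y, g, covariates = data.frame(pc1 = cov_orth))
  expect_equal(e1$beta, e0$beta, tolerance = 1e-06)
})

test_that("genotype-class percent deficits use the raw scale with delta-method errors", {
  g <- rep(c(0L, 1L, 2L), c(200, 100, 50))
  y <- c(rnorm(200, 1, 0.05), rnorm(100, 0.55, 0.05), rnorm(50, 0.06, 0.05))
  ce <- genotype_class_effects(y, g)
  expect_lt(abs(ce$het$beta - 45), 3)
  expect_lt(abs(ce$hom$beta - 94), 3)
  expect_equal(ce$het$scale, "percent_of_baseline")
  # class mean equal to non-carrier mean: deficit centred on zero
  y_null <- c(rnorm(300, 1, 0.01), rnorm(100, 1, 0.01))
  ce0 <- genotype_class_effects(y_null, rep(c(0L, 1L), c(300, 100)))
  expect_lt(abs(ce0$het$beta), 1)
  # empty homozygote class is flagged, not fatal
  expect_true(is.na(ce0$hom$beta))
  expect_equal(ce0$hom$note, "empty_class")
  expect_error(genotype_class_effects(y, rep(1L, length(y))), "non-carrier")
})

test_that("logistic estimator equals the closed-form 2x2 log odds ratio", {
  dat <- expand_2x2(10, 990, 12, 988)
  ref <- logor_2x2(10, 990, 12, 988)
  est <- fit_logistic(dat$status, dat$dose)
  expect_lt(abs(est$beta - ref$beta), 1e-06)
  expect_lt(abs(est$se - ref$se), 1e-05)
  expect_lt(abs(est$beta - log(0.8316)), 1e-04)
  expect_equal(est$n_case, 1000L)
  expect_error(fit_logistic(rep(1L, 10), rbinom(10, 2, 0.5)), "cases and controls")
  expect_error(fit_logistic(rep(0:1, 5), rep(0L, 10)), "constant")
})

test_that("flipping the effect-allele coding negates the estimate", {
  set.seed(11)
  g <- rbinom(2000, 2, 0.3)
  y <- 0.5 - 0.3 * g + rnorm(2000)
  status <- rbinom(2000, 1, plogis(-1 + 0.25 * g))
  lin <- fit_linear(y, g)
  lin_f <- fit_linear(y, 2 - g)
  expect_equal(lin_f$beta, -lin$beta, tolerance = 1e-12)
  log1 <- fit_logistic(status, g)
  log2 <- fit_logistic(status, 2 - g)
  expect_equal(log2$beta, -log1$beta, tolerance = 1e-08)
  expect_equal(log2$se, log1$se, tolerance = 1e-08)
})

test_that("separation is flagged, with an optional continuity-corrected fallback", {
  status <- rep(c(1L, 0L), c(50, 50))
  dose <- c(rep(1L, 10), rep(0L, 40), rep(0L, 50)) # all carriers are cases
  expect_error(fit_logistic(status, dose), class = "seriesmr_separation")
  cc <- fit_logistic(status, dose, continuity = TRUE)
  expect_equal(cc$note, "continuity_corrected")
  tab <- c(10, 40, 0, 50) + 0.5
  expect_equal(cc$beta, log(tab[1] * tab[4] / (tab[2] * tab[3])),
               tolerance = 1e-12)
})

test_that("a monomorphic variant yields a flagged row from the study stage, not a crash", {
  cfg <- cohort_config("S1", "EAS",
                       list(pla2g7_variants()[["Val279Phe"]],
                            variant_spec("dead", "rs0", "lof",
                                         c(EAS = 0), c(1, 0.5, 0.1))),
                       n_case = 300, n_ctrl = 300, noise_sd = 0.171, seed = 3)
  st <- assoc_study(simulate_cohort(cfg))
  dead <- st[st$variant_id == "dead", ]
  expect_true(all(is.na(dead$beta)))
  expect_true(all(dead$note == "not_estimable"))
  alive <- st[st$variant_id == "Val279Phe" & st$scale == "log_odds", ]
  expect_false(is.na(alive$beta))
})
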