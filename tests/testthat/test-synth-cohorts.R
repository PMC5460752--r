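test_that("genotypes follow Hardy-Weinberg at the configured frequencies", {
  # degenerate frequency: monomorphic column
  g0 <- simulate_genotypes(c(a = 0, b = 0.3), n = 500, seed = 1)
  expect_true(all(g0[, "a"] == 0L))

  # common variant: homozygote fraction near f^2 = 0.0225
  g <- simulate_genotypes(c(v = 0.15), n = 100000, seed = 2)
  expect_lt(abs(mean(g == 2L) - 0.0225), 0.003)

  # empirical allele frequency within binomial error for several variants
  freqs <- c(x = 0.01, y = 0.15, z = 0.80)
  gm <- simulate_genotypes(freqs, n = 50000, seed = 3)
  for (v in names(freqs)) {
    se <- sqrt(freqs[v] * (1 - freqs[v]) / (2 * 50000))
    expect_lt(abs(mean(gm[, v]) / 2 - freqs[v]), 4 * se)
  }

  # determinism: identical seed, identical matrix
  expect_identical(simulate_genotypes(freqs, 1000, seed = 9),
                   simulate_genotypes(freqs, 1000, seed = 9))
})

test_that("genotype counts pass a HWE chi-square test at the nominal rate", {
  reject <- logical(200)
  for (s in seq_len(200)) {
    g <- simulate_genotypes(c(v = 0.5), n = 5000, seed = 1000 + s)
    obs <- tabulate(g + 1L, nbins = 3L)
    expected <- 5000 * hwe_genotype_probs(0.5)
    stat <- sum((obs - expected)^2 / expected)
    reject[s] <- stat > stats::qchisq(0.95, df = 2)
  }
  # nominal 5% rejection; binomial 99% band for 200 draws is ~(0.01, 0.10)
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.10)
})

test_that("aggregate rare loss-of-function carrier frequency matches the closed form", {
  freqs <- c(`c.109+2T>C` = 5e-05, Arg82His = 4e-04, Val279Phe = 4e-04,
             Gln287Ter = 2.5e-04)
  expect_equal(carrier_probability(freqs), 1 - prod((1 - freqs)^2))
  g <- simulate_genotypes(freqs, n = 500000, forbid_multi_lof = TRUE, seed = 4)
  emp <- mean(rowSums(g) > 0L)
  expect_lt(abs(emp - carrier_probability(freqs)), 4e-04)
})

test_that("no individual carries two distinct loss-of-function variants when forbidden", {
  freqs <- c(a = 0.05, b = 0.05, c = 0.05, d = 0.05)
  g <- simulate_genotypes(freqs, n = 4000, forbid_multi_lof = TRUE, seed = 5)
  expect_true(all(rowSums(g > 0L) <= 1L))
  expect_identical(
    simulate_genotypes(freqs, 4000, forbid_multi_lof = TRUE, seed = 5), g)
})

test_that("noise calibration matches an independent numeric solve", {
  # East Asian per-allele design
  s_eas <- calibrate_noise(c(1, 0.55, 0.06), freq = 0.15,
                           target_sd_effect = 1.59)
  expect_equal(s_eas,
               oracle_noise_sd(c(1, 0.55, 0.06), hwe_genotype_probs(0.15),
                               0:2, 1.59),
               tolerance = 1e-08)
  expect_lt(abs(s_eas - 0.171), 0.001)

  # European carrier-contrast design
  s_eur <- calibrate_noise(c(1, 0.36), freq = 0.0022,
                           target_sd_effect = 2.25)
  expect_equal(s_eur,
               oracle_noise_sd(c(1, 0.36), c(1 - 0.0022, 0.0022), 0:1, 2.25),
               tolerance = 1e-08)
  expect_lt(abs(s_eur - 0.283), 0.001)

  # limit: target equal to the zero-noise effect gives sigma = 0
  probs <- hwe_genotype_probs(0.15)
  mu <- sum(probs * c(1, 0.55, 0.06))
  bv <- sum(probs * c(1, 0.55, 0.06)^2) - mu^2
  slope <- (sum(probs * 0:2 * c(1, 0.55, 0.06)) - sum(probs * 0:2) * mu) /
    (sum(probs * (0:2)^2) - sum(probs * 0:2)^2)
  expect_equal(calibrate_noise(c(1, 0.55, 0.06), 0.15, abs(slope) / sqrt(bv)),
               0, tolerance = 1e-06)
  # infeasible target
  expect_error(calibrate_noise(c(1, 0.55, 0.06), 0.15, 10), "zero-noise")
})

test_that("activity generation realizes the genotype-class means", {
  g <- simulate_genotypes(c(v = 0.3), n = 5000, seed = 6)
  m <- c(1, 0.55, 0.06)
  # noiseless: exact class means
  y0 <- simulate_activity(g, list(m), baseline_mean = 2, noise_sd = 0)
  expect_equal(y0, 2 * m[g[, 1] + 1])
  # with noise: empirical class means within 3 SE of configured values
  y <- simulate_activity(g, list(m), baseline_mean = 1, noise_sd = 0.171,
                         seed = 6)
  for (d in 0:2) {
    idx <- g[, 1] == d
    se <- 0.171 / sqrt(sum(idx))
    expect_lt(abs(mean(y[idx]) - m[d + 1]), 3 * se)
  }
  expect_identical(simulate_activity(g, list(m), 1, 0.171, seed = 6), y)
  expect_error(simulate_activity(g, list(m, m), 1, 0.1), "one activity model")
})

test_that("retrospective case-control sampling is unbiased for the configured odds ratio", {
  true_logor <- log(0.855)
  est <- se2 <- numeric(30)
  for (r in seq_len(30)) {
    st <- simulate_cc_study(c(v = 0.15), true_logor, 5000, 5000,
                            seed = 200 + r)
    fit <- fit_logistic(st$status, st$genotypes[, 1])
    est[r] <- fit$beta
    se2[r] <- fit$se^2
  }
  mc_se <- sqrt(mean(se2) / 30)
  expect_lt(abs(mean(est) - true_logor), 3 * mc_se)
})

test_that("study sets derive per-study seeds deterministically and honour tau", {
  cfg <- eas_val279phe_config(n = 2000, seed = 10)
  set1 <- simulate_study_set(list(cfg), tau = 0, seed = 10)
  expect_length(set1, 1L)
  cfg2 <- cfg; cfg2$seed <- 11L
  expect_identical(set1[[1]]$genotypes, simulate_cohort(cfg2)$genotypes)
  expect_error(simulate_study_set(list(cfg), tau = -0.1), "tau")

  # strong heterogeneity inflates Cochran's Q above its degrees of freedom
  mk <- function(i) cohort_config(paste0("S", i), "EAS",
                                  pla2g7_variants()["Val279Phe"],
                                  n_case = 2000, n_ctrl = 2000,
                                  noise_sd = 0.171, seed = 1)
  over <- logical(5)
  for (m in seq_len(5)) {
    cohorts <- simulate_study_set(lapply(1:10, mk), tau = 0.3,
                                  seed = 40 + m)
    ests <- lapply(cohorts, function(ch)
      fit_logistic(ch$status, ch$genotypes[, 1]))
    het <- heterogeneity(vapply(ests, `[[`, 0, "beta"),
                         vapply(ests, `[[`, 0, "se"))
    over[m] <- het$Q > het$df
  }
  expect_gte(sum(over), 4L)
})
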