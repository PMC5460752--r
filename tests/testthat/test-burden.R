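test_that("loss-of-function burden counts damaging alleles", {
  g <- rbind(c(1L, 0L, 0L), c(0L, 2L, 1L), c(0L, 0L, 0L))
  colnames(g) <- c("lofA", "lofB", "mis")
  bd <- lof_carrier_burden(g, c("lofA", "lofB"))
  expect_equal(bd$burden, c(1L, 2L, 0L))
  expect_equal(bd$carrier, c(1L, 1L, 0L))
  expect_equal(bd$carrier_prevalence, 2 / 3)
  z <- matrix(0L, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(lof_carrier_burden(z, c("a", "b"))$carrier_prevalence, 0)
  expect_error(lof_carrier_burden(g, character()), "at least one")
  expect_error(lof_carrier_burden(g, "missing"), "absent")
})

test_that("single-study combined test equals the logistic Rao score test", {
  set.seed(21)
  burden <- rbinom(1500, 2, 0.03)
  status <- rbinom(1500, 1, plogis(-1 + 0.4 * burden))
  sc <- burden_score_contribution(status, burden)
  res <- combine_burden_test(list(sc))
  # independent implementation: Rao score test from glm
  f0 <- glm(status ~ 1, family = binomial())
  f1 <- glm(status ~ burden, family = binomial())
  rao <- anova(f0, f1, test = "Rao")
  expect_equal(res$statistic, rao$Rao[2], tolerance = 1e-04)
  expect_equal(res$p, rao$`Pr(>Chi)`[2], tolerance = 1e-04)
})

test_that("score contributions with covariates project out the null model", {
  set.seed(22)
  x <- rnorm(800)
  burden <- rbinom(800, 2, 0.05)
  status <- rbinom(800, 1, plogis(-0.5 + 0.5 * x))
  sc <- burden_score_contribution(status, burden, covariates = cbind(x = x))
  f0 <- glm(status ~ x, family = binomial())
  f1 <- glm(status ~ x + burden, family = binomial())
  rao <- anova(f0, f1, test = "Rao")
  expect_equal(sc$U^2 / sc$V, rao$Rao[2], tolerance = 5e-04)
})

test_that("pooling identical studies scales the statistic by the study count", {
  set.seed(23)
  burden <- rbinom(500, 2, 0.05)
  status <- rbinom(500, 1, 0.3)
  sc <- burden_score_contribution(status, burden)
  two <- combine_burden_test(list(sc, sc))
  expect_equal(two$statistic, 2 * sc$U^2 / sc$V, tolerance = 1e-10)
  expect_equal(two$k, 2L)
  # constant burden: flagged warning, uninformative; all-constant errors
  expect_warning(zero <- burden_score_contribution(status, rep(0L, 500)),
                 "constant")
  expect_error(combine_burden_test(list(zero)), "undefined")
})

test_that("the combined burden test is calibrated under the null", {
  reps <- 400
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    g <- simulate_genotypes(c(a = 0.02, b = 0.02), 1000)
    status <- rbinom(1000, 1, 0.3)
    sc1 <- burden_score_contribution(status[1:500], rowSums(g)[1:500])
    sc2 <- burden_score_contribution(status[501:1000], rowSums(g)[501:1000])
    p[r] <- combine_burden_test(list(sc1, sc2))$p
  }
  t1e <- mean(p < 0.05)
  # binomial 3-sigma band around 0.05 at 400 replicates
  expect_lt(abs(t1e - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.005)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
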