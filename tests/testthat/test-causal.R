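or_from_ci <- function(or, lo, hi, n = 25000) {
  effect_estimate(log(or), (log(hi) - log(lo)) / (2 * 1.959964), n,
                  scale = "log_odds", term = "per_allele",
                  ci_lo = log(lo), ci_hi = log(hi))
}

test_that("Wald rescaling multiplies log estimate and bounds by the scale factor", {
  # null preserved
  null <- or_from_ci(1.0, 0.95, 1 / 0.95)
  expect_equal(wald_rescale(null, 1.59)$rr, 1.0, tolerance = 1e-12)

  # identity when reference equals instrument strength
  e <- or_from_ci(0.92, 0.74, 1.16)
  id <- wald_rescale(e, instrument_sd_effect = 2.26)
  expect_equal(id$rr, 0.92, tolerance = 1e-10)
  expect_equal(id$ci_lo, 0.74, tolerance = 1e-10)
  expect_equal(id$ci_hi, 1.16, tolerance = 1e-10)

  # near-unit factor: per-carrier estimate essentially unchanged (2.25 -> 2.26)
  lof <- wald_rescale(e, instrument_sd_effect = 2.25, instrument_id = "lof")
  expect_equal(round(lof$rr, 2), 0.92)
  expect_equal(round(lof$ci_lo, 2), 0.74)
  expect_equal(round(lof$ci_hi, 2), 1.16)

  # weak or wrong-signed instrument is an error, never a silent flip
  expect_error(wald_rescale(e, 0), "positive")
  expect_error(wald_rescale(e, -1.59), "positive")
  lin <- effect_estimate(-1.59, 0.01, 100, "sd_activity", "per_allele")
  expect_error(wald_rescale(lin, 1.59), "log_odds")
})

test_that("composing two rescalings equals one rescaling by the product factor", {
  e <- or_from_ci(0.97, 0.91, 1.02)
  one <- wald_rescale(e, instrument_sd_effect = 1.59, reference_sd = 2.26)
  # two steps: first to an intermediate 1 SD scale, then to 2.26 SD
  mid <- wald_rescale(e, instrument_sd_effect = 1.59, reference_sd = 1)
  mid_est <- effect_estimate(log(mid$rr),
                             (log(mid$ci_hi) - log(mid$ci_lo)) / (2 * 1.959964),
                             100, "log_odds", "per_allele",
                             ci_lo = log(mid$ci_lo), ci_hi = log(mid$ci_hi))
  two <- wald_rescale(mid_est, instrument_sd_effect = 1, reference_sd = 2.26)
  expect_equal(two$rr, one$rr, tolerance = 1e-12)
  expect_equal(two$ci_lo, one$ci_lo, tolerance = 1e-12)
  expect_equal(two$ci_hi, one$ci_hi, tolerance = 1e-12)
})

test_that("percent and SD conversions are linear, anchored and inverse", {
  expect_equal(percent_to_sd(65), 2.26, tolerance = 1e-12)
  expect_equal(percent_to_sd(0), 0)
  expect_equal(sd_to_percent(2.26), 65, tolerance = 1e-12)
  expect_equal(sd_to_percent(percent_to_sd(37.3)), 37.3, tolerance = 1e-12)
  # per-study conversions in the source data are not exactly linear:
  # 45% maps to ~1.565 SD, within 2% of the reported 1.59
  expect_equal(percent_to_sd(45), 1.59, tolerance = 0.02)
  expect_error(scale_calibration(-1, 2.26))
})

test_that("the comparison table shares one reference scale and keeps trial constants", {
  trial <- darapladib_trial()
  expect_equal(trial$rr, 0.95)
  cmp1 <- build_comparison(list(), trial)
  expect_equal(nrow(cmp1), 1L)
  expect_equal(cmp1$source, "pharmacological")

  gen <- causal_estimate("Val279Phe", 0.96, 0.87, 1.03)
  cmp <- build_comparison(list(gen), trial)
  expect_equal(nrow(cmp), 2L)
  txt <- format_comparison(cmp)
  expect_true(any(grepl("0.95 (0.89-1.02)", txt, fixed = TRUE)))

  off_scale <- causal_estimate("odd", 0.9, 0.8, 1.0, reference_sd = 1.59)
  expect_error(build_comparison(list(gen, off_scale), trial), "reference scale")
  expect_error(causal_estimate("bad", 0.9, 0.95, 1.0), "bracket")
  expect_error(causal_estimate("bad", -0.9, 0.8, 1.0), "positive")
})
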