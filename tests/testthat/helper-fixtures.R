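# Small deterministic fixtures shared across test files.

# Closed-form log odds ratio and SE from a carrier-by-status 2x2 table
# (a = case carriers, b = case non-carriers, c = control carriers,
# d = control non-carriers).
logor_2x2 <- function(a, b, c, d) {
  list(beta = log((a * d) / (b * c)), se = sqrt(1/a + 1/b + 1/c + 1/d))
}

# Expand a 2x2 table into individual-level status/dose vectors.
expand_2x2 <- function(a, b, c, d) {
  list(status = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
       dose = rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)))
}

# Independent numeric solve for the calibrated noise SD: finds sigma such
# that |slope| / sqrt(between_var + sigma^2) equals the target, with the
# moments computed by direct enumeration over the genotype classes.
oracle_noise_sd <- function(class_means, probs, dose, target) {
  mu_d <- sum(probs * dose)
  var_d <- sum(probs * dose^2) - mu_d^2
  mu_m <- sum(probs * class_means)
  bv <- sum(probs * class_means^2) - mu_m^2
  slope <- (sum(probs * dose * class_means) - mu_d * mu_m) / var_d
  f <- function(s) abs(slope) / sqrt(bv + s^2) - target
  stats::uniroot(f, c(0, 10), tol = 1e-12)$root
}
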