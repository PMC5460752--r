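#' Per-allele risk ratio implied by a target causal effect
#'
#' Inverts the Wald rescaling: a target risk ratio per reference
#' reduction in activity corresponds to a per-allele (or per-carrier)
#' risk ratio of `exp(log(target) * instrument_sd / reference_sd)`.
#'
#' @param target_rr Target risk ratio per reference reduction (e.g. 0.8
#'   for a 20% risk reduction).
#' @param instrument_sd Instrument effect on standardized activity (SD
#'   per allele or per carrier), positive.
#' @param reference_sd Reference reduction in SD units.
#' @return Per-allele risk ratio.
#' @export
#' @examples
#' per_allele_rr_from_target(0.8, 1.59, 2.26) # ~0.855
per_allele_rr_from_target <- function(target_rr, instrument_sd,
                                      reference_sd = 2.26) {
  if (any(c(target_rr, instrument_sd, reference_sd) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  exp(log(target_rr) * instrument_sd / reference_sd)
}

power_result <- function(power, alpha, maf, n_case, n_ctrl, per_allele_rr,
                         method, mc_ci = NULL, reps = NULL) {
  structure(list(power = power, alpha = alpha, maf = maf,
                 n_case = n_case, n_ctrl = n_ctrl,
                 per_allele_rr = per_allele_rr, method = method,
                 mc_ci = mc_ci, reps = reps),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> %s power = %.4f (alpha %.3g)\n", x$method,
              x$power, x$alpha))
  cat(sprintf("  maf %.4g, %d cases / %d controls, per-allele RR %.4f\n",
              x$maf, x$n_case, x$n_ctrl, x$per_allele_rr))
  if (!is.null(x$mc_ci))
    cat(sprintf("  MC 95%% CI %.3f-%.3f (%d reps)\n", x$mc_ci[1], x$mc_ci[2],
                x$reps))
  invisible(x)
}

#' Analytic power of a per-allele case-control association test
#'
#' Two-sided Wald-test power for detecting a per-allele log odds ratio,
#' using the inverse-variance approximation for the log-OR standard
#' error under Hardy-Weinberg equilibrium and independent alleles:
#' `var(log OR) = 1 / (2 n_case f (1-f)) + 1 / (2 n_ctrl f (1-f))`;
#' with `z = |log RR| / se`, power is
#' `pnorm(z - z_{1-alpha/2}) + pnorm(-z - z_{1-alpha/2})`.
#'
#' @param maf Effect-allele frequency in `(0, 1)`.
#' @param n_case,n_ctrl Case and control counts, `>= 1`.
#' @param per_allele_rr Per-allele risk ratio under the alternative.
#' @param alpha Two-sided significance level in `(0, 1)`.
#' @return A `power_result` with `method = "analytic"`.
#' @export
#' @examples
#' # East Asian Val279Phe design: >99% power for a 20% risk reduction
#' rr <- per_allele_rr_from_target(0.8, 1.59, 2.26)
#' analytic_power(0.15, 10088, 15199, rr)
analytic_power <- function(maf, n_case, n_ctrl, per_allele_rr, alpha = 0.05) {
  if (maf <= 0 || maf >= 1) stop("'maf' must lie in (0, 1)", call. = FALSE)
  if (n_case < 1 || n_ctrl < 1) stop("sample sizes must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (per_allele_rr <= 0) stop("'per_allele_rr' must be positive", call. = FALSE)
  fq <- maf * (1 - maf)
  se <- sqrt(1 / (2 * n_case * fq) + 1 / (2 * n_ctrl * fq))
  z <- abs(log(per_allele_rr)) / se
  zq <- stats::qnorm(1 - alpha / 2)
  power_result(stats::pnorm(z - zq) + stats::pnorm(-z - zq),
               alpha, maf, n_case, n_ctrl, per_allele_rr, "analytic")
}

#' Simulation-based power of the per-allele association test
#'
#' Empirical cross-check of [analytic_power()]: repeatedly simulates a
#' retrospective case-control study at the given design, fits per-allele
#' logistic regression, and reports the fraction of replicates rejecting
#' at `alpha`, with a binomial Monte-Carlo confidence interval.
#'
#' @inheritParams analytic_power
#' @param reps Number of replicate studies; at least 100 (fewer gives a
#'   Monte-Carlo interval too wide to be meaningful).
#' @param prevalence Population prevalence for the source population.
#' @param seed Integer seed.
#' @return A `power_result` with `method = "simulation"` and `mc_ci`.
#' @export
simulated_power <- function(maf, n_case, n_ctrl, per_allele_rr, alpha = 0.05,
                            reps = 500, prevalence = 0.05, seed = 1L) {
  if (reps < 100)
    stop("'reps' must be at least 100", call. = FALSE)
  logor <- log(per_allele_rr)
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    st <- simulate_cc_study(c(v = maf), logor, n_case, n_ctrl,
                            prevalence = prevalence, seed = seed + r)
    est <- fit_logistic(st$status, st$genotypes[, 1])
    reject[r] <- est$p < alpha
  }
  hits <- sum(reject)
  ci <- stats::binom.test(hits, reps)$conf.int
  power_result(hits / reps, alpha, maf, n_case, n_ctrl, per_allele_rr,
               "simulation", mc_ci = as.numeric(ci), reps = reps)
}
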