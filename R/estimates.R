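# 95% normal quantile used for every confidence interval in the package
Z95 <- 1.959964

.EST_SCALES <- c("sd_activity", "log_odds", "percent_of_baseline")
.EST_TERMS <- c("per_allele", "het_vs_ref", "hom_vs_ref", "per_carrier")

#' Construct an effect estimate
#'
#' Container for a single association result: a point estimate with its
#' standard error, normal-theory 95% confidence interval, p-value, sample
#' sizes, and tags recording the estimation scale and the genetic term the
#' estimate refers to.
#'
#' @param beta Point estimate on the estimation scale (SD of standardized
#'   activity, log odds, or percent of baseline activity).
#' @param se Standard error, `>= 0`. A zero standard error is permitted for
#'   exact (noiseless) fits; the interval then collapses to the point.
#' @param n Number of individuals contributing to the estimate.
#' @param scale One of `"sd_activity"`, `"log_odds"`,
#'   `"percent_of_baseline"`.
#' @param term One of `"per_allele"`, `"het_vs_ref"`, `"hom_vs_ref"`,
#'   `"per_carrier"`.
#' @param n_case,n_ctrl Case and control counts for binary outcomes.
#' @param note Optional free-text flag (e.g. `"continuity_corrected"`).
#' @param ci_lo,ci_hi Explicit confidence limits, for estimates imported
#'   from published tables whose intervals are not exactly symmetric on
#'   the estimation scale; by default the normal-theory bounds
#'   `beta +/- 1.959964 * se` are used.
#'
#' @return An object of class `effect_estimate`: a list with elements
#'   `beta`, `se`, `ci_lo`, `ci_hi`, `p`, `n`, `n_case`, `n_ctrl`, `scale`,
#'   `term`, `note`.
#' @export
#' @examples
#' effect_estimate(-0.157, 0.025, n = 25000, scale = "log_odds",
#'                 term = "per_allele", n_case = 10000, n_ctrl = 15000)
effect_estimate <- function(beta, se, n, scale, term,
                            n_case = NA_integer_, n_ctrl = NA_integer_,
                            note = NA_character_,
                            ci_lo = NULL, ci_hi = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number", call. = FALSE)
  if (!is.numeric(se) || length(se) != 1L || is.na(se) || se < 0)
    stop("'se' must be a single non-negative number", call. = FALSE)
  scale <- match.arg(scale, .EST_SCALES)
  term <- match.arg(term, .EST_TERMS)
  if (se > 0) {
    p <- 2 * stats::pnorm(-abs(beta) / se)
  } else {
    p <- if (beta == 0) 1 else 0
  }
  ci_lo <- if (is.null(ci_lo)) beta - Z95 * se else ci_lo
  ci_hi <- if (is.null(ci_hi)) beta + Z95 * se else ci_hi
  if (ci_lo > beta + 1e-12 || beta > ci_hi + 1e-12)
    stop("confidence limits must bracket 'beta'", call. = FALSE)
  out <- list(beta = beta, se = se,
              ci_lo = ci_lo, ci_hi = ci_hi,
              p = p, n = as.integer(n),
              n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
              scale = scale, term = term, note = note)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  val <- x$beta
  lab <- switch(x$scale,
                log_odds = "OR",
                sd_activity = "beta (SD)",
                percent_of_baseline = "percent lower")
  if (x$scale == "log_odds") {
    cat(sprintf("%s [%s]: %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d\n",
                lab, x$term, exp(val), exp(x$ci_lo), exp(x$ci_hi), x$p, x$n))
  } else {
    cat(sprintf("%s [%s]: %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d\n",
                lab, x$term, val, x$ci_lo, x$ci_hi, x$p, x$n))
  }
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ..., study_id = NA_character_,
                                          variant_id = NA_character_) {
  data.frame(study_id = study_id, variant_id = variant_id,
             term = x$term, scale = x$scale,
             beta = x$beta, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             p = x$p, n = x$n, n_case = x$n_case, n_ctrl = x$n_ctrl,
             note = x$note, stringsAsFactors = FALSE)
}

is_effect_estimate <- function(x) inherits(x, "effect_estimate")
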