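#' Reference scale linking percent and SD activity reductions
#'
#' The pharmacological reference: darapladib 160 mg once daily lowers
#' enzyme activity by 65%, equivalent to 2.26 standard deviations, so one
#' percentage point corresponds to 2.26/65 ~ 0.0348 SD (1 SD ~ 28.8%).
#'
#' @param reference_percent Percent reduction defining the scale.
#' @param reference_sd The same reduction in SD units.
#' @return Object of class `scale_calibration` with the `sd_per_percent`
#'   ratio.
#' @export
scale_calibration <- function(reference_percent = 65, reference_sd = 2.26) {
  stopifnot(reference_percent > 0, reference_sd > 0)
  structure(list(reference_percent = reference_percent,
                 reference_sd = reference_sd,
                 sd_per_percent = reference_sd / reference_percent),
            class = "scale_calibration")
}

#' Convert between percent and SD activity reductions
#'
#' Linear maps through the [scale_calibration()] ratio; the two
#' conversions are exact inverses.
#'
#' @param percent,sd Value to convert.
#' @param calibration A [scale_calibration()].
#' @return Converted value.
#' @export
#' @examples
#' percent_to_sd(65) # 2.26
#' sd_to_percent(2.26) # 65
percent_to_sd <- function(percent, calibration = scale_calibration()) {
  percent * calibration$sd_per_percent
}

#' @rdname percent_to_sd
#' @export
sd_to_percent <- function(sd, calibration = scale_calibration()) {
  sd / calibration$sd_per_percent
}

#' Construct a causal estimate on the reference scale
#'
#' A risk ratio (with 95% CI) for disease per reference reduction in the
#' exposure biomarker — by default per 65% (2.26 SD) lower activity, the
#' reduction achievable pharmacologically.
#'
#' @param instrument_id Label of the instrument (variant, burden, or
#'   drug).
#' @param rr,ci_lo,ci_hi Risk ratio and 95% confidence limits, all
#'   positive with `ci_lo <= rr <= ci_hi`.
#' @param reference_sd,reference_percent The reference reduction the
#'   ratio refers to.
#' @param source `"genetic"` or `"pharmacological"`.
#' @return Object of class `causal_estimate`.
#' @export
causal_estimate <- function(instrument_id, rr, ci_lo, ci_hi,
                            reference_sd = 2.26, reference_percent = 65,
                            source = c("genetic", "pharmacological")) {
  source <- match.arg(source)
  if (any(c(rr, ci_lo, ci_hi) <= 0))
    stop("risk ratio and confidence limits must be positive", call. = FALSE)
  if (ci_lo > rr + 1e-12 || rr > ci_hi + 1e-12)
    stop("confidence limits must bracket the risk ratio", call. = FALSE)
  structure(list(instrument_id = instrument_id, rr = rr,
                 ci_lo = ci_lo, ci_hi = ci_hi,
                 reference_sd = reference_sd,
                 reference_percent = reference_percent, source = source),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<causal_estimate> %s [%s]: RR %.2f (%.2f-%.2f) per %g%% (%g SD) lower activity\n",
              x$instrument_id, x$source, x$rr, x$ci_lo, x$ci_hi,
              x$reference_percent, x$reference_sd))
  invisible(x)
}

#' Wald-ratio rescaling of a genetic disease association
#'
#' Converts a per-allele (or per-carrier) odds ratio into the causal risk
#' ratio per reference reduction in the exposure: the log odds ratio and
#' both confidence limits are each multiplied by
#' `reference_sd / instrument_sd_effect` and exponentiated. The
#' confidence limits are transformed directly (not re-derived from a
#' delta-method standard error), mirroring how single-instrument Wald
#' estimates are reported. The odds ratio is interpreted as a risk ratio,
#' the usual rare-disease approximation.
#'
#' @param or_estimate An [effect_estimate()] on the `log_odds` scale.
#' @param instrument_sd_effect Positive magnitude of the instrument's
#'   effect on standardized activity (SD lower per allele or per
#'   carrier). A non-positive value is an error — a weak or
#'   wrong-signed instrument is never silently flipped.
#' @param reference_sd Reference reduction in SD units (default 2.26,
#'   i.e. 65%).
#' @param reference_percent Reference reduction in percent.
#' @param instrument_id Label for the returned estimate.
#' @return A [causal_estimate()] with `source = "genetic"`.
#' @export
#' @examples
#' or <- effect_estimate(log(0.97), (log(1.02) - log(0.91)) / (2 * 1.959964),
#'                       n = 25000, scale = "log_odds", term = "per_allele")
#' wald_rescale(or, instrument_sd_effect = 1.59, instrument_id = "Val279Phe")
wald_rescale <- function(or_estimate, instrument_sd_effect,
                         reference_sd = 2.26, reference_percent = 65,
                         instrument_id = "instrument") {
  if (!is_effect_estimate(or_estimate) || or_estimate$scale != "log_odds")
    stop("'or_estimate' must be an effect_estimate on the log_odds scale",
         call. = FALSE)
  if (!is.numeric(instrument_sd_effect) || instrument_sd_effect <= 0)
    stop("'instrument_sd_effect' must be positive (activity-lowering magnitude)",
         call. = FALSE)
  fac <- reference_sd / instrument_sd_effect
  causal_estimate(instrument_id,
                  rr = exp(or_estimate$beta * fac),
                  ci_lo = exp(or_estimate$ci_lo * fac),
                  ci_hi = exp(or_estimate$ci_hi * fac),
                  reference_sd = reference_sd,
                  reference_percent = reference_percent,
                  source = "genetic")
}

#' Darapladib trial effect as a causal estimate
#'
#' The pooled randomized-trial risk ratio for coronary heart disease with
#' darapladib treatment, which lowers activity by the reference 65%
#' (2.26 SD): RR 0.95 (0.89-1.02). Supplied as fixed constants for the
#' gene-versus-drug comparison.
#'
#' @param rr,ci_lo,ci_hi Trial risk ratio and confidence limits.
#' @inheritParams causal_estimate
#' @return A [causal_estimate()] with `source = "pharmacological"`.
#' @export
darapladib_trial <- function(rr = 0.95, ci_lo = 0.89, ci_hi = 1.02,
                             reference_sd = 2.26, reference_percent = 65) {
  causal_estimate("darapladib", rr, ci_lo, ci_hi,
                  reference_sd = reference_sd,
                  reference_percent = reference_percent,
                  source = "pharmacological")
}

#' Gene-versus-drug comparison table on the common scale
#'
#' Assembles the genetic causal estimates and the pharmacological trial
#' estimate into one table, one row per instrument, all expressed per the
#' same reference reduction in activity. Rows with differing reference
#' scales are refused.
#'
#' @param genetic List of [causal_estimate()] objects (may be empty).
#' @param trial A [causal_estimate()] of trial constants, or `NULL`.
#' @return data.frame with columns `instrument_id`, `source`, `rr`,
#'   `ci_lo`, `ci_hi`, `reference_percent`, `reference_sd`.
#' @export
build_comparison <- function(genetic, trial = darapladib_trial()) {
  if (inherits(genetic, "causal_estimate")) genetic <- list(genetic)
  rows <- c(genetic, if (!is.null(trial)) list(trial))
  if (length(rows) < 1L) stop("at least one estimate is required", call. = FALSE)
  ref_sd <- vapply(rows, `[[`, 0, "reference_sd")
  ref_pct <- vapply(rows, `[[`, 0, "reference_percent")
  if (length(unique(ref_sd)) != 1L || length(unique(ref_pct)) != 1L)
    stop("all rows must share the same reference scale", call. = FALSE)
  data.frame(
    instrument_id = vapply(rows, `[[`, "", "instrument_id"),
    source = vapply(rows, `[[`, "", "source"),
    rr = vapply(rows, `[[`, 0, "rr"),
    ci_lo = vapply(rows, `[[`, 0, "ci_lo"),
    ci_hi = vapply(rows, `[[`, 0, "ci_hi"),
    reference_percent = ref_pct, reference_sd = ref_sd,
    stringsAsFactors = FALSE)
}

# two decimals, half away from zero (printed-table style; sprintf rounds
# half to even, so do it explicitly)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render the comparison table as aligned text
#'
#' @param comparison A [build_comparison()] data.frame.
#' @return Character vector of lines (also printed when at the console).
#' @export
format_comparison <- function(comparison) {
  fmt <- function(x) sprintf("%.2f", round_half_up(x, 2))
  body <- sprintf("%-22s %-16s %s (%s-%s)",
                  comparison$instrument_id, comparison$source,
                  fmt(comparison$rr), fmt(comparison$ci_lo),
                  fmt(comparison$ci_hi))
  header <- sprintf("Risk ratio for CHD per %g%% (%g SD) lower Lp-PLA2 activity",
                    comparison$reference_percent[1],
                    comparison$reference_sd[1])
  c(header, strrep("-", nchar(header)), body)
}
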