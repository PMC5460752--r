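#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study-level estimates on a common scale with weights
#' `w_i = 1 / se_i^2`: pooled beta `sum(w b) / sum(w)`, pooled standard
#' error `1 / sqrt(sum(w))`, normal-theory confidence interval and
#' p-value. Heterogeneity (Cochran's Q, I-squared, heterogeneity p) is
#' attached when two or more studies contribute; with a single study the
#' heterogeneity fields are absent (`NA`), not zero.
#'
#' @param estimates List of [effect_estimate()] objects sharing `scale`
#'   and `term`, all with `se > 0`.
#' @return Object of class `meta_result`: list with `pooled` (an
#'   [effect_estimate()]), `k`, `Q`, `df`, `i2` (percent), `p_het`.
#' @export
#' @examples
#' e1 <- effect_estimate(0.1, 0.1, 100, "log_odds", "per_allele")
#' e2 <- effect_estimate(0.3, 0.1, 100, "log_odds", "per_allele")
#' fixed_effect_pool(list(e1, e2))$pooled$beta # 0.2
fixed_effect_pool <- function(estimates) {
  if (is_effect_estimate(estimates)) estimates <- list(estimates)
  k <- length(estimates)
  if (k < 1L) stop("at least one estimate is required", call. = FALSE)
  stopifnot(all(vapply(estimates, is_effect_estimate, TRUE)))
  scales <- unique(vapply(estimates, `[[`, "", "scale"))
  terms <- unique(vapply(estimates, `[[`, "", "term"))
  if (length(scales) != 1L || length(terms) != 1L)
    stop("estimates must share a common scale and term", call. = FALSE)
  b <- vapply(estimates, `[[`, 0, "beta")
  se <- vapply(estimates, `[[`, 0, "se")
  if (any(se <= 0))
    stop("all standard errors must be positive for pooling", call. = FALSE)
  w <- 1 / se^2
  beta_p <- sum(w * b) / sum(w)
  se_p <- 1 / sqrt(sum(w))
  pooled <- effect_estimate(
    beta_p, se_p,
    n = sum(vapply(estimates, `[[`, 0L, "n")),
    scale = scales, term = terms,
    n_case = sum_or_na(vapply(estimates, `[[`, NA_integer_, "n_case")),
    n_ctrl = sum_or_na(vapply(estimates, `[[`, NA_integer_, "n_ctrl")))
  het <- if (k >= 2L) heterogeneity(b, se) else
    list(Q = NA_real_, df = NA_integer_, i2 = NA_real_, p_het = NA_real_)
  structure(c(list(pooled = pooled, k = k), het), class = "meta_result")
}

sum_or_na <- function(x) if (all(is.na(x))) NA_integer_ else sum(x, na.rm = TRUE)

#' Heterogeneity statistics for a set of study estimates
#'
#' Cochran's `Q = sum w_i (b_i - pooled)^2` with fixed-effect weights,
#' its chi-square p-value on `k - 1` degrees of freedom, and the
#' I-squared statistic `max(0, (Q - df) / Q) * 100` (0 when `Q = 0`),
#' the percentage of between-study variability attributable to
#' heterogeneity rather than chance.
#'
#' @param betas Study point estimates on a common scale.
#' @param ses Study standard errors, all `> 0`.
#' @return List with `Q`, `df`, `i2` (percent in `[0, 100]`), `p_het`.
#' @export
#' @examples
#' heterogeneity(c(0, 1), c(0.5, 0.5)) # Q = 2, I2 = 50%
heterogeneity <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L)
    stop("heterogeneity is undefined for fewer than 2 studies", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  df <- k - 1L
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, i2 = i2,
       p_het = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d studies\n", x$k))
  print(x$pooled)
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.3f (df %d), I2 = %.1f%%, p_het = %.3g\n",
                x$Q, x$df, x$i2, x$p_het))
  invisible(x)
}

#' Pool a per-study summary-statistic table
#'
#' Groups a summary-statistic table (the TSV contract between the
#' association, meta-analysis and causal stages) by variant, term and
#' scale, pools each group by fixed-effect meta-analysis, and returns the
#' pooled rows with `study_id = "POOLED"` plus heterogeneity columns.
#'
#' @param stats A data.frame in the summary-statistic schema (see
#'   [assoc_study()]).
#' @return data.frame of pooled rows with columns `Q`, `df`, `i2`,
#'   `p_het` appended.
#' @export
pool_summary_stats <- function(stats) {
  stats <- stats[!is.na(stats$beta) & !is.na(stats$se) & stats$se > 0, ]
  groups <- unique(stats[, c("variant_id", "term", "scale")])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    rows <- stats[stats$variant_id == g$variant_id &
                    stats$term == g$term & stats$scale == g$scale, ]
    ests <- lapply(seq_len(nrow(rows)), function(r)
      effect_estimate(rows$beta[r], rows$se[r], rows$n[r],
                      scale = rows$scale[r], term = rows$term[r],
                      n_case = rows$n_case[r], n_ctrl = rows$n_ctrl[r]))
    mr <- fixed_effect_pool(ests)
    row <- as.data.frame(mr$pooled, study_id = "POOLED",
                         variant_id = g$variant_id)
    row$k <- mr$k; row$Q <- mr$Q; row$df <- mr$df
    row$i2 <- mr$i2; row$p_het <- mr$p_het
    out[[i]] <- row
  }
  do.call(rbind, out)
}
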