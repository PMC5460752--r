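#' Standardize a biomarker to z-scores
#'
#' Centres and scales activity values using the mean and unbiased
#' (n-1 denominator) standard deviation of a reference group: all
#' individuals, or controls only. Control-only standardization avoids
#' case-enrichment distortion in case-control studies.
#'
#' @param values Numeric vector of raw biomarker values.
#' @param reference `"all"` or `"controls"`.
#' @param status Required when `reference = "controls"`: 1/0 case-control
#'   indicator aligned with `values`.
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' standardize_activity(c(1, 2, 3)) # -1, 0, 1
standardize_activity <- function(values, reference = c("all", "controls"),
                                 status = NULL) {
  reference <- match.arg(reference)
  ref <- if (reference == "controls") {
    if (is.null(status)) stop("'status' needed for reference = \"controls\"",
                              call. = FALSE)
    values[status == 0L]
  } else {
    values
  }
  ref <- ref[is.finite(ref)]
  if (length(unique(ref)) < 2L)
    stop("reference group has fewer than 2 distinct finite values",
         call. = FALSE)
  s <- stats::sd(ref)
  if (s == 0) stop("zero variance in reference group", call. = FALSE)
  (values - mean(ref)) / s
}

#' Linear association of a quantitative phenotype with allele dose
#'
#' Ordinary least-squares regression of a (typically standardized)
#' phenotype on allele count or carrier status, with optional covariates
#' partialled out; classical standard errors. With the effect allele
#' defined as the activity-lowering allele, the slope is negative for the
#' biomarker; the magnitude is `abs(beta)`.
#'
#' @param pheno Numeric phenotype vector (z-scores for `"sd_activity"`).
#' @param dose Allele counts (0/1/2) or carrier indicator (0/1).
#' @param covariates Optional numeric matrix or data.frame of covariates.
#' @param scale Scale tag for the returned estimate.
#' @param term Term tag (`"per_allele"` or `"per_carrier"`).
#' @return An [effect_estimate()].
#' @export
fit_linear <- function(pheno, dose, covariates = NULL,
                       scale = "sd_activity", term = "per_allele") {
  if (length(unique(dose)) < 2L)
    stop("'dose' is constant; association undefined", call. = FALSE)
  df <- data.frame(.y = pheno, .dose = dose)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design in linear fit", call. = FALSE)
  sm <- suppressWarnings(summary(fit))$coefficients
  b <- sm[".dose", "Estimate"]
  se <- sm[".dose", "Std. Error"]
  if (!is.finite(se)) se <- 0   # saturated / noiseless exact fit
  effect_estimate(b, se, n = length(pheno), scale = scale, term = term)
}

#' Genotype-class activity deficits relative to non-carriers
#'
#' Percent-lower activity of heterozygotes and homozygotes compared with
#' non-carriers, computed on the raw (unstandardized) scale:
#' `100 * (1 - mean_class / mean_noncarrier)`, with a delta-method
#' standard error from the class means and variances. An empty genotype
#' class yields an `NA` estimate flagged in `note`, not an error.
#'
#' @param activity Raw activity values.
#' @param genotypes Integer 0/1/2 dosage vector for one variant.
#' @return List with elements `het` and `hom`, each an
#'   [effect_estimate()] on the `percent_of_baseline` scale (or `NA`
#'   beta with `note = "empty_class"`).
#' @export
genotype_class_effects <- function(activity, genotypes) {
  if (sum(genotypes == 0L) == 0L)
    stop("no non-carrier reference individuals", call. = FALSE)
  ref <- activity[genotypes == 0L]
  m0 <- mean(ref); v0 <- stats::var(ref); n0 <- length(ref)
  one_class <- function(g_val, term) {
    x <- activity[genotypes == g_val]
    if (length(x) < 2L) {
      est <- effect_estimate(0, 1, n = n0 + length(x),
                             scale = "percent_of_baseline", term = term,
                             note = "empty_class")
      est$beta <- NA_real_; est$se <- NA_real_
      est$ci_lo <- NA_real_; est$ci_hi <- NA_real_; est$p <- NA_real_
      return(est)
    }
    m1 <- mean(x); v1 <- stats::var(x); n1 <- length(x)
    ratio <- m1 / m0
    # delta method on the ratio of two independent sample means
    var_ratio <- ratio^2 * (v1 / (n1 * m1^2) + v0 / (n0 * m0^2))
    effect_estimate(100 * (1 - ratio), 100 * sqrt(var_ratio),
                    n = n0 + n1, scale = "percent_of_baseline", term = term)
  }
  list(het = one_class(1L, "het_vs_ref"), hom = one_class(2L, "hom_vs_ref"))
}

#' Logistic association of disease with allele dose
#'
#' Maximum-likelihood logistic regression of case-control status on
#' allele count or carrier status with optional covariates, fitted by
#' iteratively reweighted least squares (convergence tolerance 1e-10,
#' at most 50 iterations); Wald standard error from the observed
#' information.
#'
#' Complete or quasi-complete separation (monotone likelihood) is
#' detected and raised as an error of class `seriesmr_separation`. With
#' `continuity = TRUE` a separated binary-exposure fit instead collapses
#' the data to the carrier-by-status 2x2 table, adds 0.5 to every cell,
#' and returns the corrected log odds ratio marked
#' `note = "continuity_corrected"`.
#'
#' @param status 1/0 case-control indicator.
#' @param dose Allele counts or carrier indicator.
#' @param covariates Optional numeric matrix or data.frame.
#' @param term Term tag for the returned estimate.
#' @param continuity Fall back to the 0.5-corrected 2x2 estimate on
#'   separation (binary dose, no covariates only).
#' @return An [effect_estimate()] on the `log_odds` scale.
#' @export
fit_logistic <- function(status, dose, covariates = NULL,
                         term = "per_allele", continuity = FALSE) {
  if (length(unique(status[!is.na(status)])) < 2L)
    stop("both cases and controls are required", call. = FALSE)
  if (length(unique(dose)) < 2L)
    stop("'dose' is constant; association undefined", call. = FALSE)
  df <- data.frame(.y = status, .dose = dose)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  b <- stats::coef(fit)[".dose"]
  separated <- !fit$converged || abs(b) > 10 ||
    (any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8)) &&
      abs(b) > 8
  if (separated) {
    if (continuity && is.null(covariates) && all(dose %in% c(0, 1))) {
      tab <- table(factor(dose, levels = 0:1), factor(status, levels = 0:1)) + 0.5
      b2 <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
      se2 <- sqrt(sum(1 / tab))
      return(effect_estimate(b2, se2, n = length(status), scale = "log_odds",
                             term = term, n_case = sum(status == 1L),
                             n_ctrl = sum(status == 0L),
                             note = "continuity_corrected"))
    }
    stop(structure(class = c("seriesmr_separation", "error", "condition"),
                   list(message = "complete or quasi-complete separation in logistic fit",
                        call = NULL)))
  }
  se <- summary(fit)$coefficients[".dose", "Std. Error"]
  effect_estimate(unname(b), se, n = length(status), scale = "log_odds",
                  term = term, n_case = sum(status == 1L),
                  n_ctrl = sum(status == 0L))
}

#' Per-individual loss-of-function allele burden
#'
#' Collapses the rare loss-of-function variants into a single count of
#' damaging alleles per individual; the carrier prevalence is the
#' fraction of individuals with burden >= 1.
#'
#' @param genotypes Dosage matrix with named columns.
#' @param lof_ids Character vector of loss-of-function variant columns.
#' @return List with `burden` (integer vector), `carrier` (0/1 indicator)
#'   and `carrier_prevalence`.
#' @export
lof_carrier_burden <- function(genotypes, lof_ids) {
  if (length(lof_ids) < 1L)
    stop("at least one loss-of-function variant is required", call. = FALSE)
  missing <- setdiff(lof_ids, colnames(genotypes))
  if (length(missing))
    stop("loss-of-function variants absent from genotypes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  burden <- as.integer(rowSums(genotypes[, lof_ids, drop = FALSE]))
  carrier <- as.integer(burden >= 1L)
  list(burden = burden, carrier = carrier,
       carrier_prevalence = mean(carrier))
}
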