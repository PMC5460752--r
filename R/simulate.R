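#' Hardy-Weinberg genotype probabilities
#'
#' @param freq Effect-allele frequency in `[0, 1]`.
#' @return Numeric vector `c(p0, p1, p2)` of genotype probabilities for
#'   0, 1 and 2 copies of the effect allele under random mating.
#' @export
#' @examples
#' hwe_genotype_probs(0.15) # homozygote probability 0.0225
hwe_genotype_probs <- function(freq) {
  stopifnot(is.numeric(freq), length(freq) == 1L, freq >= 0, freq <= 1)
  c(p0 = (1 - freq)^2, p1 = 2 * freq * (1 - freq), p2 = freq^2)
}

#' Aggregate carrier probability across independent variants
#'
#' Probability that an individual carries at least one effect allele at
#' any of several independent variants in Hardy-Weinberg equilibrium:
#' `1 - prod((1 - f_i)^2)`.
#'
#' @param freqs Numeric vector of effect-allele frequencies.
#' @return Single probability.
#' @export
#' @examples
#' # the four rare loss-of-function alleles: ~0.2% of people carry one
#' carrier_probability(c(5e-05, 4e-04, 4e-04, 2.5e-04))
carrier_probability <- function(freqs) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  1 - prod((1 - freqs)^2)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each variant column is drawn independently as Binomial(2, f): the HWE
#' genotype distribution at effect-allele frequency f. With
#' `forbid_multi_lof`, individuals carrying alleles at more than one
#' distinct loss-of-function variant are redrawn until compliant, which
#' emulates the observed mutual exclusivity of rare loss-of-function
#' carriers.
#'
#' @param freqs Named numeric vector of effect-allele frequencies (names
#'   become the column names).
#' @param n Number of individuals, `>= 1`.
#' @param forbid_multi_lof If `TRUE`, no individual may carry alleles at
#'   two or more of the variants flagged in `lof`.
#' @param lof Logical vector (or character vector of names) marking which
#'   variants count as loss-of-function for the multi-carrier constraint;
#'   defaults to all variants.
#' @param seed Optional integer seed; the output is fully reproducible
#'   given the seed.
#' @return Integer matrix of 0/1/2 dosages, `n` rows by
#'   `length(freqs)` columns.
#' @export
#' @examples
#' g <- simulate_genotypes(c(Val279Phe = 0.15), n = 1000, seed = 1)
#' mean(g == 2) # about 0.0225
simulate_genotypes <- function(freqs, n, forbid_multi_lof = FALSE,
                               lof = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (any(freqs < 0 | freqs > 1))
    stop("all frequencies must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  k <- length(freqs)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(NULL, names(freqs)))
  for (j in seq_len(k)) g[, j] <- stats::rbinom(n, 2L, freqs[j])
  if (forbid_multi_lof && k > 1L) {
    if (is.null(lof)) {
      lof_idx <- seq_len(k)
    } else if (is.character(lof)) {
      lof_idx <- match(lof, colnames(g))
      if (anyNA(lof_idx)) stop("unknown lof variant name", call. = FALSE)
    } else {
      lof_idx <- which(lof)
    }
    repeat {
      bad <- which(rowSums(g[, lof_idx, drop = FALSE] > 0L) > 1L)
      if (length(bad) == 0L) break
      for (j in lof_idx)
        g[bad, j] <- stats::rbinom(length(bad), 2L, freqs[j])
    }
  }
  g
}

#' Calibrate within-class noise to a target standardized effect
#'
#' Solves, in closed form, for the within-genotype-class noise standard
#' deviation (as a fraction of the baseline mean) that makes the
#' standardized regression slope of the simulated biomarker on allele
#' count (or carrier status) equal a target value in SD units.
#'
#' Under the generator's model the raw per-unit slope is
#' `b = cov(g, mu_g) / var(g)` where `mu_g` are the genotype-class means,
#' and the total biomarker variance is the between-class variance plus the
#' noise variance `sigma^2`. The standardized effect is
#' `|b| / sqrt(between_var + sigma^2)`, giving
#' `sigma = sqrt((b / target)^2 - between_var)`. No truncation correction
#' is applied, consistent with the untruncated Gaussian noise model of
#' [simulate_activity()].
#'
#' @param class_means Genotype-class mean multipliers. Length 3
#'   (`m0, m1, m2`, per-allele coding 0/1/2) or length 2
#'   (`m_noncarrier, m_carrier`, carrier coding 0/1).
#' @param freq For length-3 `class_means`, the effect-allele frequency
#'   (class probabilities from Hardy-Weinberg); for length 2, the carrier
#'   frequency.
#' @param target_sd_effect Desired absolute standardized slope, in SD
#'   units of the biomarker.
#' @return Noise standard deviation as a fraction of the baseline mean.
#'   Zero when the target equals the zero-noise standardized effect; an
#'   error when the target exceeds it.
#' @export
#' @examples
#' calibrate_noise(c(1, 0.55, 0.06), freq = 0.15, target_sd_effect = 1.59)
#' calibrate_noise(c(1, 0.36), freq = 0.0022, target_sd_effect = 2.25)
calibrate_noise <- function(class_means, freq, target_sd_effect) {
  stopifnot(target_sd_effect > 0, freq >= 0, freq <= 1)
  if (length(class_means) == 3L) {
    probs <- hwe_genotype_probs(freq)
    dose <- 0:2
  } else if (length(class_means) == 2L) {
    probs <- c(1 - freq, freq)
    dose <- 0:1
  } else {
    stop("'class_means' must have length 2 or 3", call. = FALSE)
  }
  mu_d <- sum(probs * dose)
  var_d <- sum(probs * dose^2) - mu_d^2
  if (var_d <= 0)
    stop("degenerate genotype distribution: dose has zero variance",
         call. = FALSE)
  mu_m <- sum(probs * class_means)
  between_var <- sum(probs * class_means^2) - mu_m^2
  slope <- (sum(probs * dose * class_means) - mu_d * mu_m) / var_d
  max_effect <- abs(slope) / sqrt(between_var)
  sigma2 <- (slope / target_sd_effect)^2 - between_var
  if (sigma2 < -1e-12)
    stop(sprintf(paste0("target standardized effect %.4g exceeds the ",
                        "zero-noise limit %.4g"),
                 target_sd_effect, max_effect), call. = FALSE)
  sqrt(max(sigma2, 0))
}

#' Simulate biomarker activity from genotypes
#'
#' Each individual's activity is the baseline mean times the product of
#' the genotype-class multipliers of their genotypes across variants,
#' plus Gaussian noise with standard deviation `noise_sd * baseline_mean`.
#' Multipliers combine multiplicatively across variants; at the rare
#' frequencies of interest, multi-variant carriers essentially never occur
#' so this choice is inconsequential but well defined.
#'
#' By default the Gaussian noise is not truncated, so values below zero
#' can occur for classes whose mean is within a few noise SDs of zero.
#' This keeps the closed-form calibration of [calibrate_noise()] and the
#' genotype-class means exact. Set `truncate = TRUE` to left-censor at
#' zero when strictly non-negative measured values are required (this
#' biases near-zero class means upward).
#'
#' @param genotypes Integer matrix of 0/1/2 dosages.
#' @param activity_models List (one per variant column) of length-3
#'   multiplier vectors `c(m0, m1, m2)`, or a single vector recycled when
#'   there is one variant.
#' @param baseline_mean Non-carrier mean activity in raw units.
#' @param noise_sd Noise SD as a fraction of `baseline_mean`, `>= 0`.
#' @param truncate Left-censor at zero (default `FALSE`).
#' @param seed Optional integer seed.
#' @return Numeric vector of activity values, one per row of `genotypes`.
#' @export
simulate_activity <- function(genotypes, activity_models, baseline_mean = 1,
                              noise_sd, truncate = FALSE, seed = NULL) {
  if (is.numeric(activity_models)) activity_models <- list(activity_models)
  if (length(activity_models) != ncol(genotypes))
    stop("need one activity model per genotype column", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mult <- rep(1, nrow(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    m <- activity_models[[j]]
    if (length(m) != 3L) stop("each activity model must be c(m0, m1, m2)",
                              call. = FALSE)
    mult <- mult * m[genotypes[, j] + 1L]
  }
  y <- baseline_mean * mult
  if (noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, noise_sd * baseline_mean)
  if (truncate) y <- pmax(y, 0)
  y
}

#' Assign disease status and draw a case-control sample from a pool
#'
#' Disease probability follows an additive (per-allele) logistic model:
#' `logit P(D) = a0 + sum_j g_j * logOR_j`, with the intercept chosen so
#' the population prevalence is approximately `prevalence` (the genetic
#' score is centred at its population mean). Cases and controls are then
#' sampled without replacement from the pool — retrospective sampling,
#' which preserves the per-allele odds ratio.
#'
#' @param genotypes Pool genotype matrix (0/1/2 dosages).
#' @param per_allele_logor Numeric vector of per-allele log odds ratios,
#'   one per variant column (recycled if length 1).
#' @param n_case,n_ctrl Numbers of cases and controls to sample, `>= 1`.
#' @param prevalence Population disease prevalence used for the model
#'   intercept.
#' @param seed Optional integer seed.
#' @return List with `index` (row indices of the sampled individuals,
#'   cases first) and `status` (1 = case, 0 = control, aligned with
#'   `index`).
#' @export
simulate_case_control <- function(genotypes, per_allele_logor, n_case, n_ctrl,
                                  prevalence = 0.05, seed = NULL) {
  if (n_case < 1 || n_ctrl < 1)
    stop("'n_case' and 'n_ctrl' must both be >= 1", call. = FALSE)
  k <- ncol(genotypes)
  if (length(per_allele_logor) == 1L) per_allele_logor <- rep(per_allele_logor, k)
  if (length(per_allele_logor) != k)
    stop("need one log odds ratio per variant column", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  score <- as.numeric(genotypes %*% per_allele_logor)
  eta <- stats::qlogis(prevalence) + score - mean(score)
  y <- stats::rbinom(nrow(genotypes), 1L, stats::plogis(eta))
  cases <- which(y == 1L)
  ctrls <- which(y == 0L)
  if (length(cases) < n_case || length(ctrls) < n_ctrl)
    stop(sprintf("pool too small: %d cases / %d controls available, %d / %d requested",
                 length(cases), length(ctrls), n_case, n_ctrl), call. = FALSE)
  idx <- c(sample(cases, n_case), sample(ctrls, n_ctrl))
  list(index = idx, status = rep(c(1L, 0L), c(n_case, n_ctrl)))
}

#' Simulate a complete case-control genotype study
#'
#' Convenience wrapper: generates a source population large enough to
#' contain the requested numbers of cases and controls at the stated
#' prevalence, assigns disease under the additive logistic model, and
#' returns the retrospective sample.
#'
#' @inheritParams simulate_case_control
#' @inheritParams simulate_genotypes
#' @param margin Oversampling factor for the source-population size.
#' @return List with `genotypes` (sampled rows) and `status`.
#' @export
simulate_cc_study <- function(freqs, per_allele_logor, n_case, n_ctrl,
                              prevalence = 0.05, forbid_multi_lof = FALSE,
                              lof = NULL, seed = NULL, margin = 1.3) {
  if (!is.null(seed)) set.seed(seed)
  pool_n <- ceiling(margin * max(n_case / prevalence, n_ctrl / (1 - prevalence)))
  for (attempt in 1:5) {
    g <- simulate_genotypes(freqs, pool_n, forbid_multi_lof = forbid_multi_lof,
                            lof = lof)
    cc <- tryCatch(
      simulate_case_control(g, per_allele_logor, n_case, n_ctrl,
                            prevalence = prevalence),
      error = function(e) NULL)
    if (!is.null(cc))
      return(list(genotypes = g[cc$index, , drop = FALSE], status = cc$status))
    pool_n <- ceiling(pool_n * 1.5)   # shortfall: enlarge and retry
  }
  stop("failed to generate enough cases/controls", call. = FALSE)
}

#' Configuration of one simulated study cohort
#'
#' Bundles everything [simulate_cohort()] needs: design (cohort of size
#' `n`, or case-control with `n_case`/`n_ctrl`), the variants carried,
#' the activity-noise level, the disease model, and the seed, which fully
#' determines the simulated data.
#'
#' @param study_id Study label.
#' @param ancestry `"EUR"`, `"SAS"` or `"EAS"`; selects the
#'   ancestry-specific effect-allele frequency of each variant.
#' @param variants Named list of [variant_spec()] objects.
#' @param n Cohort size (cohort design), or `NULL` for case-control.
#' @param n_case,n_ctrl Case-control design sample sizes.
#' @param baseline_activity_mean Non-carrier mean activity, raw units.
#' @param noise_sd Within-class activity noise SD as a fraction of the
#'   baseline mean; must be `> 0` when activity is generated.
#' @param per_allele_logor Named numeric vector of per-allele log odds
#'   ratios on disease (missing variants default to 0).
#' @param prevalence Baseline disease prevalence.
#' @param forbid_multi_lof Disallow carriers of two distinct
#'   loss-of-function variants (default `TRUE`, matching observation).
#' @param truncate_activity Left-censor activity at zero (default
#'   `FALSE`; see [simulate_activity()]).
#' @param seed Integer seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(study_id, ancestry, variants,
                          n = NULL, n_case = NULL, n_ctrl = NULL,
                          baseline_activity_mean = 1, noise_sd,
                          per_allele_logor = NULL, prevalence = 0.05,
                          forbid_multi_lof = TRUE, truncate_activity = FALSE,
                          seed = 1L) {
  ancestry <- match.arg(ancestry, c("EUR", "SAS", "EAS"))
  if (is.null(n) == is.null(n_case))
    stop("give either 'n' (cohort) or 'n_case' + 'n_ctrl' (case-control)",
         call. = FALSE)
  if (!is.null(n_case) && (is.null(n_ctrl) || n_case < 1 || n_ctrl < 1))
    stop("case-control design needs n_case >= 1 and n_ctrl >= 1", call. = FALSE)
  if (!is.null(n) && n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be > 0 when activity is generated",
                          call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must lie in (0, 1)", call. = FALSE)
  vids <- vapply(variants, `[[`, "", "variant_id")
  names(variants) <- vids
  logor <- stats::setNames(rep(0, length(vids)), vids)
  if (!is.null(per_allele_logor)) {
    unknown <- setdiff(names(per_allele_logor), vids)
    if (length(unknown))
      stop("per_allele_logor names not in variant list: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    logor[names(per_allele_logor)] <- per_allele_logor
  }
  structure(list(study_id = study_id, ancestry = ancestry,
                 variants = variants, n = n, n_case = n_case, n_ctrl = n_ctrl,
                 baseline_activity_mean = baseline_activity_mean,
                 noise_sd = noise_sd, per_allele_logor = logor,
                 prevalence = prevalence, forbid_multi_lof = forbid_multi_lof,
                 truncate_activity = truncate_activity,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an individual-level study cohort
#'
#' Realizes a [cohort_config()]: genotypes under Hardy-Weinberg
#' equilibrium at the ancestry-specific frequencies, biomarker activity
#' from the genotype-class model, and disease status under the additive
#' logistic model — either prospectively (cohort design) or by
#' retrospective case-control sampling from a large source population.
#'
#' @param config A [cohort_config()].
#' @return Object of class `study_cohort`: list with `study_id`,
#'   `ancestry`, `genotypes` (individuals x variants), `activity`,
#'   `status` (1/0), `covariates` (`NULL` unless attached later), and the
#'   generating `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  freqs <- vapply(config$variants, function(v) {
    f <- v$effect_allele_freq[[config$ancestry]]
    if (is.null(f) || is.na(f))
      stop(sprintf("variant %s has no frequency for ancestry %s",
                   v$variant_id, config$ancestry), call. = FALSE)
    f
  }, 0)
  models <- lapply(config$variants, `[[`, "activity_model")
  lof <- vapply(config$variants, function(v) v$var_class == "lof", TRUE)
  set.seed(config$seed)
  if (!is.null(config$n)) {
    g <- simulate_genotypes(freqs, config$n,
                            forbid_multi_lof = config$forbid_multi_lof,
                            lof = lof)
    score <- as.numeric(g %*% config$per_allele_logor)
    eta <- stats::qlogis(config$prevalence) + score - mean(score)
    status <- stats::rbinom(nrow(g), 1L, stats::plogis(eta))
  } else {
    cc <- simulate_cc_study(freqs, config$per_allele_logor,
                            config$n_case, config$n_ctrl,
                            prevalence = config$prevalence,
                            forbid_multi_lof = config$forbid_multi_lof,
                            lof = lof)
    g <- cc$genotypes
    status <- cc$status
  }
  activity <- simulate_activity(g, models,
                                baseline_mean = config$baseline_activity_mean,
                                noise_sd = config$noise_sd,
                                truncate = config$truncate_activity)
  structure(list(study_id = config$study_id, ancestry = config$ancestry,
                 genotypes = g, activity = activity, status = status,
                 covariates = NULL, config = config),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %s (%s): %d individuals, %d variants\n",
              x$study_id, x$ancestry, nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  cases %d / controls %d\n", sum(x$status == 1L),
              sum(x$status == 0L)))
  invisible(x)
}

#' Simulate a set of studies with optional between-study heterogeneity
#'
#' Each study's true per-allele log odds ratios are drawn from
#' `Normal(configured value, tau^2)` — one study-level deviate applied to
#' every variant — and its seed is derived deterministically from the
#' master seed as `seed + study index`, so the whole set is reproducible.
#'
#' @param configs List of [cohort_config()] objects.
#' @param tau Between-study SD of the true log odds ratios, `>= 0`.
#' @param seed Master integer seed.
#' @return List of `study_cohort` objects.
#' @export
simulate_study_set <- function(configs, tau = 0, seed = 1L) {
  if (tau < 0) stop("'tau' must be >= 0", call. = FALSE)
  if (length(configs) < 1L) stop("need at least one study config", call. = FALSE)
  set.seed(seed)
  deltas <- stats::rnorm(length(configs), 0, tau)
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg$per_allele_logor <- cfg$per_allele_logor + deltas[i]
    cfg$seed <- as.integer(seed + i)
    out[[i]] <- simulate_cohort(cfg)
  }
  names(out) <- vapply(out, `[[`, "", "study_id")
  out
}

#' Canned East Asian Val279Phe cohort configuration
#'
#' The reference simulated study for the common loss-of-function variant:
#' Val279Phe at effect-allele frequency 0.15, genotype-class activity
#' means 1.00/0.55/0.06 of baseline, and within-class noise SD 0.171 of
#' baseline — the value calibrated (see [calibrate_noise()]) so the
#' per-allele effect on standardized activity is 1.59 SD.
#'
#' @param n Cohort size (default 20000).
#' @param seed Integer seed.
#' @param per_allele_logor Per-allele log odds ratio on disease for
#'   Val279Phe (default 0).
#' @return A [cohort_config()].
#' @export
eas_val279phe_config <- function(n = 20000, seed = 1L, per_allele_logor = 0) {
  v <- pla2g7_variants()["Val279Phe"]
  cohort_config("EAS_sim", "EAS", v, n = n, noise_sd = 0.171,
                per_allele_logor = c(Val279Phe = per_allele_logor),
                seed = seed)
}

#' Canned European rare loss-of-function cohort configuration
#'
#' The reference simulated study for the rare loss-of-function alleles:
#' the four variants at effect-allele frequencies 0.005%, 0.04%, 0.04%
#' and 0.025% (aggregate carrier frequency ~0.2%), carrier activity mean
#' 0.36 of baseline, and within-class noise SD 0.283 of baseline — the
#' value calibrated so the per-carrier effect on standardized activity is
#' 2.25 SD.
#'
#' @param n Cohort size (default 100000).
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
eur_lof_config <- function(n = 100000, seed = 1L) {
  v <- pla2g7_variants()[c("c.109+2T>C", "Arg82His", "Val279Phe", "Gln287Ter")]
  for (i in seq_along(v)) v[[i]]$activity_model <- c(1, 0.36, 0.13)
  cohort_config("EUR_sim", "EUR", v, n = n, noise_sd = 0.283, seed = seed)
}
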