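na_stat_row <- function(study_id, variant_id, term, scale, n, note,
                        n_case = NA_integer_, n_ctrl = NA_integer_) {
  data.frame(study_id = study_id, variant_id = variant_id, term = term,
             scale = scale, beta = NA_real_, se = NA_real_, ci_lo = NA_real_,
             ci_hi = NA_real_, p = NA_real_, n = n, n_case = n_case,
             n_ctrl = n_ctrl, note = note, stringsAsFactors = FALSE)
}

#' Per-study association summary statistics
#'
#' Runs the full within-study association stage on one cohort and
#' returns rows in the summary-statistic schema (`study_id`,
#' `variant_id`, `term`, `scale`, `beta`, `se`, `ci_lo`, `ci_hi`, `p`,
#' `n`, `n_case`, `n_ctrl`, `note`): per variant, the per-allele linear
#' effect on standardized activity, the heterozygote and homozygote
#' percent deficits, and the per-allele log odds ratio for disease; and,
#' when `lof_ids` is given, per-carrier linear and logistic effects of
#' the loss-of-function burden under the pseudo-variant id
#' `"LOF_BURDEN"`.
#'
#' Activity is standardized against controls in case-control studies and
#' against everyone in cohort studies. A variant that is monomorphic or
#' separated in this study yields a flagged `NA` row rather than an
#' error.
#'
#' @param cohort A `study_cohort`.
#' @param lof_ids Loss-of-function variant columns to collapse into a
#'   burden, or `NULL` to skip the burden rows.
#' @param covariates Optional covariate matrix passed to every fit.
#' @return data.frame of summary-statistic rows.
#' @export
assoc_study <- function(cohort, lof_ids = NULL, covariates = NULL) {
  g <- cohort$genotypes
  status <- cohort$status
  is_cc <- !is.null(cohort$config$n_case) ||
    (is.null(cohort$config) && length(unique(stats::na.omit(status))) == 2L)
  ref <- if (is_cc) "controls" else "all"
  z <- standardize_activity(cohort$activity, reference = ref, status = status)
  n <- nrow(g)
  n_case <- sum(status == 1L, na.rm = TRUE)
  n_ctrl <- sum(status == 0L, na.rm = TRUE)
  sid <- cohort$study_id
  rows <- list()
  add <- function(est, variant_id) {
    r <- as.data.frame(est, study_id = sid, variant_id = variant_id)
    rows[[length(rows) + 1L]] <<- r
  }
  add_try <- function(expr, variant_id, term, scale) {
    est <- tryCatch(expr, error = function(e) e)
    if (inherits(est, "error")) {
      note <- if (inherits(est, "seriesmr_separation")) "separation"
              else "not_estimable"
      rows[[length(rows) + 1L]] <<- na_stat_row(sid, variant_id, term, scale,
                                                n, note, n_case, n_ctrl)
    } else add(est, variant_id)
  }
  for (v in colnames(g)) {
    dose <- g[, v]
    add_try(fit_linear(z, dose, covariates), v, "per_allele", "sd_activity")
    if (any(dose > 0L)) {
      ce <- genotype_class_effects(cohort$activity, dose)
      add(ce$het, v)
      add(ce$hom, v)
    }
    if (length(unique(stats::na.omit(status))) == 2L)
      add_try(fit_logistic(status, dose, covariates), v, "per_allele",
              "log_odds")
  }
  if (!is.null(lof_ids) && length(lof_ids)) {
    bd <- lof_carrier_burden(g, lof_ids)
    add_try(fit_linear(z, bd$carrier, covariates, term = "per_carrier"),
            "LOF_BURDEN", "per_carrier", "sd_activity")
    if (length(unique(stats::na.omit(status))) == 2L)
      add_try(fit_logistic(status, bd$carrier, covariates,
                           term = "per_carrier"),
              "LOF_BURDEN", "per_carrier", "log_odds")
  }
  do.call(rbind, rows)
}

#' Assemble an end-to-end analysis configuration
#'
#' @param studies List of [cohort_config()] objects and/or character
#'   paths to study tables in the [write_study_table()] schema.
#' @param variants Variant registry; every variant referenced by a study
#'   or instrument must resolve here (checked up front).
#' @param instruments List of instrument descriptors, each a list with
#'   `id`, `type` (`"per_allele"` or `"per_carrier"`), and either
#'   `variant` (a registered variant id) or `lof` (variant ids collapsed
#'   into the burden); an optional `ancestries` element restricts the
#'   power calculation to studies of those ancestries (useful when a
#'   variant is common in one ancestry and rare elsewhere).
#' @param trial Trial constants as a [causal_estimate()], or `NULL`.
#' @param reference A [scale_calibration()].
#' @param target_rr Target causal risk ratio for the power calculation.
#' @param alpha Two-sided significance level for power.
#' @param lof_ancestries Ancestries in which the rare loss-of-function
#'   burden is analysed (default Europeans and South Asians, where the
#'   alleles are rare).
#' @param tau Between-study SD of true log odds ratios for simulated
#'   studies.
#' @param seed Master seed; recorded in all outputs.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(studies, variants = pla2g7_variants(),
                            instruments, trial = darapladib_trial(),
                            reference = scale_calibration(),
                            target_rr = 0.8, alpha = 0.05,
                            lof_ancestries = c("EUR", "SAS"),
                            tau = 0, seed = 1L) {
  for (ins in instruments) {
    vids <- c(ins$variant, ins$lof)
    unknown <- setdiff(vids, names(variants))
    if (length(unknown))
      stop("instrument '", ins$id, "' references unregistered variant(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (st in studies) {
    if (inherits(st, "cohort_config")) {
      unknown <- setdiff(names(st$variants), names(variants))
      if (length(unknown))
        stop("study '", st$study_id, "' uses unregistered variant(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(studies = studies, variants = variants,
                 instruments = instruments, trial = trial,
                 reference = reference, target_rr = target_rr,
                 alpha = alpha, lof_ancestries = lof_ancestries,
                 tau = tau, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Demonstration analysis configuration
#'
#' A small self-contained analysis: two East Asian case-control studies
#' of Val279Phe, and one European cohort study carrying the four rare
#' loss-of-function variants plus Val379Ala, all simulated under the
#' null (no allele affects disease). Instruments: per-allele Val279Phe,
#' per-allele Val379Ala, and the per-carrier loss-of-function burden;
#' compared against the darapladib trial constants.
#'
#' @param seed Master seed.
#' @return An [analysis_config()].
#' @export
demo_analysis_config <- function(seed = 1L) {
  reg <- pla2g7_variants()
  eas1 <- cohort_config("EAS_cc_1", "EAS", reg["Val279Phe"],
                        n_case = 3000, n_ctrl = 3000, noise_sd = 0.171,
                        seed = seed)
  eas2 <- cohort_config("EAS_cc_2", "EAS", reg["Val279Phe"],
                        n_case = 3000, n_ctrl = 3000, noise_sd = 0.171,
                        seed = seed)
  eur_vars <- reg[c("c.109+2T>C", "Arg82His", "Val279Phe", "Gln287Ter",
                    "Val379Ala")]
  for (v in c("c.109+2T>C", "Arg82His", "Val279Phe", "Gln287Ter"))
    eur_vars[[v]]$activity_model <- c(1, 0.36, 0.13)
  eur <- cohort_config("EUR_cohort", "EUR", eur_vars, n = 40000,
                       noise_sd = 0.283, seed = seed)
  analysis_config(
    studies = list(eas1, eas2, eur),
    variants = reg,
    instruments = list(
      list(id = "Val279Phe", type = "per_allele", variant = "Val279Phe",
           ancestries = "EAS"),
      list(id = "Val379Ala", type = "per_allele", variant = "Val379Ala"),
      list(id = "lof_burden", type = "per_carrier",
           lof = c("c.109+2T>C", "Arg82His", "Val279Phe", "Gln287Ter"))),
    seed = seed)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Reads a configuration file describing studies (simulated or on disk),
#' instruments, trial constants and the reference scale, and builds the
#' corresponding [analysis_config()]. Simulated-study entries name
#' registered variants; frequencies and activity models come from the
#' registry unless overridden per study.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [analysis_config()].
#' @export
load_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  reg <- pla2g7_variants()
  studies <- lapply(raw$studies, function(st) {
    if (is.character(st)) return(st)
    if (!is.null(st$path)) return(st$path)
    vars <- reg[resolve_variant_alias(unlist(st$variants), reg)]
    if (!is.null(st$activity_model_override)) {
      for (nm in names(st$activity_model_override))
        vars[[nm]]$activity_model <- as.numeric(st$activity_model_override[[nm]])
    }
    cohort_config(st[["study_id"]], st[["ancestry"]], vars,
                  n = st[["n_individuals"]], n_case = st[["n_case"]],
                  n_ctrl = st[["n_ctrl"]],
                  baseline_activity_mean = st[["baseline_activity_mean"]] %||% 1,
                  noise_sd = st[["noise_sd"]],
                  per_allele_logor = unlist(st[["per_allele_logor"]]),
                  prevalence = st[["prevalence"]] %||% 0.05,
                  seed = st[["seed"]] %||% 1L)
  })
  instruments <- lapply(raw$instruments, function(ins)
    list(id = ins[["id"]], type = ins[["type"]],
         variant = ins[["variant"]], lof = unlist(ins[["lof"]]),
         ancestries = unlist(ins[["ancestries"]])))
  trial <- if (is.null(raw$trial)) darapladib_trial() else
    causal_estimate(raw$trial$id %||% "darapladib", raw$trial$rr,
                    raw$trial$ci_lo, raw$trial$ci_hi,
                    reference_sd = raw$reference$sd %||% 2.26,
                    reference_percent = raw$reference$percent %||% 65,
                    source = "pharmacological")
  reference <- scale_calibration(raw$reference$percent %||% 65,
                                 raw$reference$sd %||% 2.26)
  analysis_config(studies, reg, instruments, trial, reference,
                  target_rr = raw$power$target_rr %||% 0.8,
                  alpha = raw$power$alpha %||% 0.05,
                  tau = raw$tau %||% 0, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full allelic-series analysis pipeline
#'
#' Executes every stage on the configured studies — simulate or load,
#' per-study association, fixed-effect meta-analysis, the combined
#' loss-of-function burden score test, Wald-ratio rescaling onto the
#' reference scale, the gene-versus-drug comparison, and analytic power
#' — and writes the artifact bundle to `out_dir`: `summary_stats.tsv`,
#' `pooled_stats.tsv`, `comparison.tsv`, `comparison.json`,
#' `power.json`, and `run_log.txt`. Output is deterministic given the
#' configuration seed.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the cohorts, summary and pooled
#'   tables, the combined burden test, the causal comparison, the power
#'   results, and the written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate/ingest"
  on_fail <- function(e, what) {
    stop(sprintf("pipeline stage '%s' failed for %s: %s", stage, what,
                 conditionMessage(e)), call. = FALSE)
  }

  sim_cfgs <- Filter(function(s) inherits(s, "cohort_config"), config$studies)
  paths <- Filter(is.character, config$studies)
  cohorts <- list()
  if (length(sim_cfgs))
    cohorts <- simulate_study_set(sim_cfgs, tau = config$tau,
                                  seed = config$seed)
  for (p in paths) {
    ch <- tryCatch(load_study_table(p, config$variants),
                   error = function(e) on_fail(e, p))
    cohorts[[ch$study_id]] <- ch
  }

  stage <- "associate"
  lof_reg <- names(Filter(function(v) v$var_class == "lof", config$variants))
  stats_rows <- list()
  contribs <- list()
  for (ch in cohorts) {
    lof_here <- if (ch$ancestry %in% config$lof_ancestries)
      intersect(lof_reg, colnames(ch$genotypes)) else NULL
    if (length(lof_here) == 0L) lof_here <- NULL
    st <- tryCatch(assoc_study(ch, lof_ids = lof_here),
                   error = function(e) on_fail(e, ch$study_id))
    stats_rows[[ch$study_id]] <- st
    if (!is.null(lof_here) &&
        length(unique(stats::na.omit(ch$status))) == 2L) {
      bd <- lof_carrier_burden(ch$genotypes, lof_here)
      contribs[[ch$study_id]] <- suppressWarnings(
        burden_score_contribution(ch$status, bd$burden,
                                  study_id = ch$study_id))
    }
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  stage <- "meta-analyse"
  pooled <- tryCatch(pool_summary_stats(stats),
                     error = function(e) on_fail(e, "pooling"))
  burden_test <- if (length(contribs))
    combine_burden_test(contribs) else NULL

  stage <- "rescale"
  genetic <- list()
  for (ins in config$instruments) {
    vid <- if (ins$type == "per_carrier") "LOF_BURDEN" else ins$variant
    term <- if (ins$type == "per_carrier") "per_carrier" else "per_allele"
    act <- pooled[pooled$variant_id == vid & pooled$term == term &
                    pooled$scale == "sd_activity", ]
    orr <- pooled[pooled$variant_id == vid & pooled$term == term &
                    pooled$scale == "log_odds", ]
    if (nrow(act) != 1L || nrow(orr) != 1L) {
      warning("instrument '", ins$id,
              "' lacks pooled activity or disease estimates; skipped",
              call. = FALSE)
      next
    }
    or_est <- effect_estimate(orr$beta, orr$se, orr$n, scale = "log_odds",
                              term = term, n_case = orr$n_case,
                              n_ctrl = orr$n_ctrl)
    genetic[[ins$id]] <- tryCatch(
      wald_rescale(or_est, instrument_sd_effect = abs(act$beta),
                   reference_sd = config$reference$reference_sd,
                   reference_percent = config$reference$reference_percent,
                   instrument_id = ins$id),
      error = function(e) on_fail(e, ins$id))
  }

  stage <- "compare"
  comparison <- build_comparison(unname(genetic), config$trial)

  stage <- "power"
  power <- list()
  for (ins in config$instruments) {
    if (ins$type != "per_allele") next
    vid <- ins$variant
    rowset <- stats[stats$variant_id == vid & stats$scale == "log_odds" &
                      !is.na(stats$beta), ]
    if (!is.null(ins$ancestries)) {
      keep <- vapply(rowset$study_id, function(s)
        cohorts[[s]]$ancestry %in% ins$ancestries, TRUE)
      rowset <- rowset[keep, , drop = FALSE]
    }
    if (nrow(rowset) == 0L) next
    sids <- unique(rowset$study_id)
    doses <- unlist(lapply(cohorts[sids], function(ch)
      ch$genotypes[ch$status == 0L, vid]))
    maf <- mean(doses) / 2
    if (maf <= 0 || maf >= 1) next
    act <- pooled[pooled$variant_id == vid & pooled$term == "per_allele" &
                    pooled$scale == "sd_activity", ]
    rr <- per_allele_rr_from_target(config$target_rr, abs(act$beta),
                                    config$reference$reference_sd)
    power[[ins$id]] <- analytic_power(maf, sum(rowset$n_case),
                                      sum(rowset$n_ctrl), rr,
                                      alpha = config$alpha)
  }

  stage <- "write"
  p_stats <- file.path(out_dir, "summary_stats.tsv")
  p_pooled <- file.path(out_dir, "pooled_stats.tsv")
  p_cmp <- file.path(out_dir, "comparison.tsv")
  p_cmp_json <- file.path(out_dir, "comparison.json")
  p_power <- file.path(out_dir, "power.json")
  p_log <- file.path(out_dir, "run_log.txt")
  write_summary_stats(stats, p_stats)
  write_summary_stats(pooled, p_pooled)
  utils::write.table(comparison, p_cmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  jsonlite::write_json(comparison, p_cmp_json, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(power, unclass), p_power, auto_unbox = TRUE,
                       digits = NA)
  writeLines(c(
    sprintf("seriesmr %s on R %s.%s", as.character(utils::packageVersion("seriesmr")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", config$seed),
    sprintf("studies: %d (%s)", length(cohorts),
            paste(names(cohorts), collapse = ", ")),
    sprintf("individuals: %d",
            sum(vapply(cohorts, function(ch) nrow(ch$genotypes), 0L))),
    sprintf("summary rows: %d; pooled rows: %d", nrow(stats), nrow(pooled)),
    if (!is.null(burden_test))
      sprintf("combined burden test: chi2(1) = %.4f, p = %.4g across %d studies",
              burden_test$statistic, burden_test$p, burden_test$k)
    else "combined burden test: not run",
    format_comparison(comparison)), p_log)

  invisible(list(cohorts = cohorts, stats = stats, pooled = pooled,
                 burden_test = burden_test, genetic = genetic,
                 comparison = comparison, power = power,
                 paths = c(summary = p_stats, pooled = p_pooled,
                           comparison = p_cmp, comparison_json = p_cmp_json,
                           power = p_power, log = p_log)))
}
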