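# Full-precision numeric serialization for TSV output: values survive a
# write/read round trip to better than 1e-10 relative error.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

SUMMARY_COLS <- c("study_id", "variant_id", "term", "scale", "beta", "se",
                  "ci_lo", "ci_hi", "p", "n", "n_case", "n_ctrl", "note")

#' Write a study cohort as a TSV table
#'
#' One row per individual with columns `individual_id`, `study_id`,
#' `ancestry`, `status` (1/0/NA), `activity`, then one 0/1/2 dosage
#' column per variant. UTF-8, Unix newlines, dot decimal, `NA` for
#' missing. The generating configuration is echoed as a YAML sidecar
#' (`<path>.yaml`) when the cohort carries one.
#'
#' @param cohort A `study_cohort`.
#' @param path Output file path.
#' @param sidecar Write the YAML config echo (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(cohort, path, sidecar = TRUE) {
  g <- cohort$genotypes
  df <- data.frame(individual_id = seq_len(nrow(g)),
                   study_id = cohort$study_id,
                   ancestry = cohort$ancestry,
                   status = cohort$status,
                   activity = fmt_num(cohort$activity),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8", eol = "\n")
  if (sidecar && !is.null(cohort$config)) {
    cfg <- cohort$config
    echo <- list(study_id = cfg$study_id, ancestry = cfg$ancestry,
                 n = cfg$n, n_case = cfg$n_case, n_ctrl = cfg$n_ctrl,
                 baseline_activity_mean = cfg$baseline_activity_mean,
                 noise_sd = cfg$noise_sd,
                 per_allele_logor = as.list(cfg$per_allele_logor),
                 prevalence = cfg$prevalence,
                 forbid_multi_lof = cfg$forbid_multi_lof,
                 truncate_activity = cfg$truncate_activity,
                 seed = cfg$seed,
                 variants = names(cfg$variants))
    yaml::write_yaml(echo, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Load a study cohort from a TSV table
#'
#' Parses and validates a table in the [write_study_table()] schema.
#' Variant columns may be named by canonical id, rsid, or a configured
#' proxy alias (e.g. a column `rs1805018` resolves to Val279Phe).
#' Malformed content — a missing header column, a dosage outside
#' \{0, 1, 2\}, a status outside \{0, 1, NA\} — raises a descriptive
#' error naming the offending line and column.
#'
#' @param path Input TSV path.
#' @param variants Variant registry used for alias resolution; `NULL`
#'   skips resolution and keeps column names as found.
#' @param aliases Alias map (see [default_alias_map()]).
#' @return A `study_cohort` (with `config = NULL`).
#' @export
load_study_table <- function(path, variants = pla2g7_variants(),
                             aliases = default_alias_map(variants)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("individual_id", "study_id", "ancestry", "status", "activity")
  missing <- setdiff(fixed, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  var_cols <- setdiff(names(df), fixed)
  if (length(var_cols) == 0L)
    stop("no variant dosage columns found", call. = FALSE)
  if (!is.null(variants))
    var_ids <- resolve_variant_alias(var_cols, variants, aliases)
  else
    var_ids <- var_cols
  bad_status <- which(!(df$status %in% c(0L, 1L, NA)))
  if (length(bad_status))
    stop(sprintf("invalid status value '%s' at line %d",
                 df$status[bad_status[1]], bad_status[1] + 1L), call. = FALSE)
  g <- matrix(0L, nrow = nrow(df), ncol = length(var_cols),
              dimnames = list(NULL, var_ids))
  for (j in seq_along(var_cols)) {
    v <- df[[var_cols[j]]]
    bad <- which(!(v %in% c(0L, 1L, 2L)))
    if (length(bad))
      stop(sprintf("invalid dosage value '%s' at line %d, column '%s'",
                   v[bad[1]], bad[1] + 1L, var_cols[j]), call. = FALSE)
    g[, j] <- as.integer(v)
  }
  structure(list(study_id = df$study_id[1], ancestry = df$ancestry[1],
                 genotypes = g, activity = as.numeric(df$activity),
                 status = as.integer(df$status), covariates = NULL,
                 config = NULL),
            class = "study_cohort")
}

#' Write / read a summary-statistic table
#'
#' The per-study summary-statistic TSV (one row per study x variant x
#' term) is the contract between the association, meta-analysis and
#' causal stages. Numeric columns are serialized at full precision.
#'
#' @param stats data.frame in the summary-statistic schema.
#' @param path File path.
#' @return `path` invisibly (writer); the parsed data.frame (reader).
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(all(SUMMARY_COLS %in% names(stats)))
  out <- stats[, SUMMARY_COLS[SUMMARY_COLS %in% names(stats)], drop = FALSE]
  extra <- setdiff(names(stats), SUMMARY_COLS)
  out <- cbind(out, stats[, extra, drop = FALSE])
  num <- vapply(out, is.numeric, TRUE) &
    !(names(out) %in% c("n", "n_case", "n_ctrl", "k", "df"))
  for (j in which(num)) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(SUMMARY_COLS, names(df))
  if (length(missing))
    stop("summary-statistic table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Export cohort genotypes as a minimal VCF
#'
#' GT-only VCF 4.2 with one record per variant and one sample column per
#' individual; dosage d is written as the unphased genotype with d
#' effect (ALT) alleles. Positions are nominal (record order) — the
#' export carries genotypes, not coordinates.
#'
#' @param cohort A `study_cohort`.
#' @param path Output path.
#' @param variants Registry supplying rsids for the ID column.
#' @return `path`, invisibly.
#' @export
export_genotypes_vcf <- function(cohort, path, variants = pla2g7_variants()) {
  g <- cohort$genotypes
  n <- nrow(g)
  ids <- colnames(g)
  rsid <- vapply(ids, function(v)
    if (v %in% names(variants)) variants[[v]]$rsid else v, "")
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=seriesmr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", seq_len(n))),
                     collapse = "\t")), con)
  for (j in seq_along(ids)) {
    row <- c("6", as.character(j), rsid[j], "N", "A", ".", "PASS", ".", "GT",
             gt[g[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
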