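#' Define a functional variant
#'
#' A `variant_spec` describes one functional variant of the target gene:
#' its identifiers, functional class, ancestry-specific effect-allele
#' frequencies, and the genotype-class activity model used by the cohort
#' simulator. The activity model gives the mean biomarker level of each
#' genotype class (0, 1 or 2 effect alleles) as a multiplier of the
#' non-carrier baseline; by convention the non-carrier multiplier is 1.
#'
#' The effect allele is always the activity-lowering allele, so
#' loss-of-function variants must have non-increasing class multipliers
#' (`m2 <= m1 <= m0 = 1`).
#'
#' @param variant_id Short identifier used in column names (e.g.
#'   `"Val279Phe"`).
#' @param rsid dbSNP identifier.
#' @param var_class `"lof"` (loss of function) or `"missense"`.
#' @param effect_allele_freq Named numeric vector of effect-allele
#'   frequencies by ancestry label (`EUR`, `SAS`, `EAS`), each in `[0, 1]`.
#' @param activity_model Numeric vector `c(m0, m1, m2)` of genotype-class
#'   mean multipliers, each in `[0, 1.5]`, with `m0 = 1`.
#' @param aliases Character vector of alternative rsids that should resolve
#'   to this variant (proxy names in external tables).
#'
#' @return An object of class `variant_spec`.
#' @export
#' @examples
#' variant_spec("Val279Phe", "rs76863441", "lof",
#'              c(EUR = 4e-4, SAS = 4e-4, EAS = 0.15),
#'              activity_model = c(1, 0.55, 0.06),
#'              aliases = "rs1805018")
variant_spec <- function(variant_id, rsid, var_class,
                         effect_allele_freq,
                         activity_model = c(1, 1, 1),
                         aliases = character()) {
  var_class <- match.arg(var_class, c("lof", "missense"))
  if (is.null(names(effect_allele_freq)) || any(!nzchar(names(effect_allele_freq))))
    stop("'effect_allele_freq' must be a named vector (ancestry labels)",
         call. = FALSE)
  if (any(effect_allele_freq < 0 | effect_allele_freq > 1))
    stop("effect-allele frequencies must lie in [0, 1]", call. = FALSE)
  if (length(activity_model) != 3L)
    stop("'activity_model' must be c(m0, m1, m2)", call. = FALSE)
  if (any(activity_model < 0 | activity_model > 1.5))
    stop("activity-model multipliers must lie in [0, 1.5]", call. = FALSE)
  if (abs(activity_model[1] - 1) > 1e-12)
    stop("non-carrier multiplier m0 must be 1 by convention", call. = FALSE)
  if (var_class == "lof" && (activity_model[3] > activity_model[2] + 1e-12 ||
                             activity_model[2] > activity_model[1] + 1e-12))
    stop("lof variants must have m2 <= m1 <= m0 (activity-lowering)",
         call. = FALSE)
  structure(list(variant_id = variant_id, rsid = rsid,
                 var_class = var_class,
                 effect_allele_freq = effect_allele_freq,
                 activity_model = as.numeric(activity_model),
                 aliases = as.character(aliases)),
            class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s (%s), class %s\n", x$variant_id, x$rsid,
              x$var_class))
  cat("  freq:", paste(sprintf("%s=%g", names(x$effect_allele_freq),
                               x$effect_allele_freq), collapse = ", "), "\n")
  cat("  activity multipliers:", paste(x$activity_model, collapse = "/"), "\n")
  invisible(x)
}

#' Registry of PLA2G7 functional variants
#'
#' The five functional variants of the Lp-PLA2 gene used throughout the
#' package: four rare loss-of-function alleles (a splice-site mutation,
#' two activity-ablating missense changes, and a nonsense variant) and one
#' common modest-impact missense variant. Effect-allele frequencies are
#' ancestry specific: the loss-of-function alleles are rare (0.005%-0.04%)
#' in Europeans and South Asians, Val279Phe is common (15%) in East Asians,
#' and the Val379Ala effect allele has about 80% frequency in Europeans.
#'
#' Genotype-class activity multipliers encode the observed biomarker
#' deficits: Val279Phe heterozygotes about 45% lower and homozygotes about
#' 94% lower enzyme activity than non-carriers; the remaining
#' loss-of-function carriers about 64% lower; Val379Ala about 2.7% lower
#' per allele.
#'
#' @return Named list of [variant_spec()] objects.
#' @export
#' @examples
#' names(pla2g7_variants())
pla2g7_variants <- function() {
  v <- list(
    variant_spec("c.109+2T>C", "rs142974898", "lof",
                 c(EUR = 5e-05, SAS = 5e-05, EAS = 0),
                 activity_model = c(1, 0.36, 0.13)),
    variant_spec("Arg82His", "rs144983904", "lof",
                 c(EUR = 4e-04, SAS = 4e-04, EAS = 0),
                 activity_model = c(1, 0.36, 0.13)),
    variant_spec("Val279Phe", "rs76863441", "lof",
                 c(EUR = 4e-04, SAS = 4e-04, EAS = 0.15),
                 activity_model = c(1, 0.55, 0.06),
                 aliases = "rs1805018"),
    variant_spec("Gln287Ter", "rs140020965", "lof",
                 c(EUR = 2.5e-04, SAS = 2.5e-04, EAS = 0),
                 activity_model = c(1, 0.36, 0.13)),
    variant_spec("Val379Ala", "rs1051931", "missense",
                 c(EUR = 0.80, SAS = 0.80, EAS = 0.80),
                 activity_model = c(1, 0.973, 0.946),
                 aliases = c("rs7756935", "rs3799277"))
  )
  names(v) <- vapply(v, `[[`, "", "variant_id")
  v
}

#' Alias map for proxy variant names
#'
#' Maps alternative rsids (proxy variants genotyped in some studies) to
#' the canonical rsid of the registered variant they tag, e.g.
#' `rs1805018` is accepted as a name for Val279Phe. Only exact name
#' aliasing is supported; no linkage-disequilibrium imputation is done.
#'
#' @param variants Named list of [variant_spec()] objects.
#' @return Named character vector: `alias -> variant_id`.
#' @export
default_alias_map <- function(variants = pla2g7_variants()) {
  out <- character()
  for (v in variants) {
    nm <- c(v$rsid, v$aliases)
    out[nm] <- v$variant_id
  }
  out
}

#' Resolve variant column names through the alias map
#'
#' @param names Character vector of variant names as found in a table
#'   header (variant ids, rsids, or proxy rsids).
#' @param variants Named list of [variant_spec()] objects.
#' @param aliases Alias map as returned by [default_alias_map()].
#' @return Character vector of canonical `variant_id`s; unresolvable names
#'   raise an error.
#' @export
resolve_variant_alias <- function(names, variants = pla2g7_variants(),
                                  aliases = default_alias_map(variants)) {
  out <- character(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    if (nm %in% names(variants)) {
      out[i] <- nm
    } else if (nm %in% names(aliases)) {
      out[i] <- aliases[[nm]]
    } else {
      stop(sprintf("variant name '%s' is not registered and has no alias", nm),
           call. = FALSE)
    }
  }
  out
}
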