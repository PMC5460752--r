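#' Per-study score contribution for the combined burden test
#'
#' Computes the logistic score statistic for association of a
#' loss-of-function burden with disease in one study, in the exchangeable
#' form used by seqMeta-style cross-study tests: under the null model
#' (covariates only, or intercept only), `U = sum_i burden_i (y_i - yhat_i)`
#' and `V` is the variance of `U` from the null-model information,
#' `V = b' W b - b' W X (X' W X)^-1 X' W b` with `W = diag(yhat (1 - yhat))`.
#'
#' @param status 1/0 case-control indicator.
#' @param burden Per-individual damaging-allele counts.
#' @param covariates Optional numeric matrix or data.frame for the null
#'   model.
#' @param study_id Optional label carried through to the result.
#' @return Object of class `score_contribution`: list with `study_id`,
#'   `U`, `V`, `n`, `n_case`, `n_ctrl`. A constant burden gives `V = 0`
#'   (flagged with a warning), which carries no information but can still
#'   be pooled.
#' @export
burden_score_contribution <- function(status, burden, covariates = NULL,
                                      study_id = NA_character_) {
  if (length(status) != length(burden))
    stop("'status' and 'burden' lengths differ", call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, length(status)))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (ncol(X) > 1L) {
    null_fit <- suppressWarnings(
      stats::glm.fit(X, status, family = stats::binomial()))
    phat <- null_fit$fitted.values
  } else {
    phat <- rep(mean(status), length(status))
  }
  U <- sum(burden * (status - phat))
  w <- phat * (1 - phat)
  XtWX <- crossprod(X * w, X)
  bWX <- crossprod(burden * w, X)
  V <- sum(burden^2 * w) - as.numeric(bWX %*% solve(XtWX, t(bWX)))
  if (V <= 1e-12) {
    warning("burden is constant in study ", study_id,
            ": score contribution carries no information", call. = FALSE)
    V <- 0
  }
  structure(list(study_id = study_id, U = U, V = V, n = length(status),
                 n_case = sum(status == 1L), n_ctrl = sum(status == 0L)),
            class = "score_contribution")
}

#' Combined burden score test across studies
#'
#' Pools per-study score contributions into the one-degree-of-freedom
#' chi-square statistic `(sum U)^2 / sum V`, testing the null hypothesis
#' of no association between the loss-of-function burden and disease in
#' any study.
#'
#' @param contributions List of [burden_score_contribution()] results.
#' @return List with `statistic`, `df` (= 1), `p`, `k` (study count) and
#'   total sample sizes.
#' @export
combine_burden_test <- function(contributions) {
  if (inherits(contributions, "score_contribution"))
    contributions <- list(contributions)
  U <- vapply(contributions, `[[`, 0, "U")
  V <- vapply(contributions, `[[`, 0, "V")
  if (sum(V) <= 0)
    stop("burden is constant in every study: combined test undefined",
         call. = FALSE)
  stat <- sum(U)^2 / sum(V)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       k = length(contributions),
       n = sum(vapply(contributions, `[[`, 0L, "n")),
       n_case = sum(vapply(contributions, `[[`, 0L, "n_case")),
       n_ctrl = sum(vapply(contributions, `[[`, 0L, "n_ctrl")))
}
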