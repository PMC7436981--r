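#' Tidy a fitted fear-of-falling logistic model
#'
#' @param x A `fof_logistic` object from [fit_logistic()].
#' @param ... Ignored.
#' @return A tibble with one row per term (`intercept`, `slope`), the
#'   estimate on the log-odds scale, the odds ratio and its 95% CI for the
#'   slope, and the Wald p value.
#' @method tidy fof_logistic
#' @export
tidy.fof_logistic <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$beta0, x$beta1),
    odds_ratio = c(NA_real_, x$odds_ratio),
    or_lo = c(NA_real_, x$or_ci95[1L]),
    or_hi = c(NA_real_, x$or_ci95[2L]),
    p_value = c(NA_real_, x$p_value))
}

#' @rdname tidy.fof_logistic
#' @return For `glance()`: a one-row tibble with `log_lik`, `n`,
#'   `converged`, `separation` and the small-sample corrected AIC.
#' @method glance fof_logistic
#' @export
glance.fof_logistic <- function(x, ...) {
  tibble::tibble(log_lik = x$log_lik, n = x$n, converged = x$converged,
                 separation = x$separation,
                 caic = caic(x$log_lik, 2L, x$n))
}

#' Tidy an ROC analysis
#'
#' @param x A `cop_roc` object from [roc_analysis()].
#' @param ... Ignored.
#' @return The per-threshold curve as a tibble (`threshold`, `sensitivity`,
#'   `specificity`, `j`).
#' @method tidy cop_roc
#' @export
tidy.cop_roc <- function(x, ...) {
  dplyr::mutate(x$curve, j = .data$sensitivity + .data$specificity - 1)
}

#' @rdname tidy.cop_roc
#' @return For `glance()`: a one-row tibble with the AUC, its CI, the
#'   orientation and the Youden point.
#' @method glance cop_roc
#' @export
glance.cop_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci95[1L], auc_hi = x$auc_ci95[2L],
                 orientation = x$orientation,
                 youden_cutoff = x$youden_cutoff,
                 youden_sens = x$youden_sens, youden_spec = x$youden_spec,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
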