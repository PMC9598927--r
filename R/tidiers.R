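#' Tidy a differential-expression table
#'
#' @param x A `de_table` from [call_de()].
#' @param ... Unused.
#' @return The per-feature records as a plain tibble.
#' @method tidy de_table
#' @export
tidy.de_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_table")
  attr(out, "thresholds") <- NULL
  out
}

#' One-row summary of a differential-expression table
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return Tibble with feature and up/down/DE counts plus the thresholds
#'   used.
#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  dplyr::bind_cols(
    de_counts(x),
    tibble::tibble(p_max = th$p_max, neg_log_fdr_min = th$neg_log_fdr_min,
                   abs_log2fc_min = th$abs_log2fc_min, rule = th$rule)
  )
}

#' Tidy a survival fit into Kaplan-Meier steps
#'
#' @param x A `cerna_survfit` from [survival_fit()].
#' @param ... Unused.
#' @return Tibble of KM steps per expression group.
#' @method tidy cerna_survfit
#' @export
tidy.cerna_survfit <- function(x, ...) x$km

#' One-row summary of a survival fit
#'
#' @param x A `cerna_survfit`.
#' @param ... Unused.
#' @return Tibble with the gene, cutpoint, event counts, hazard ratio
#'   with CI, and the log-rank test.
#' @method glance cerna_survfit
#' @export
glance.cerna_survfit <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, cutpoint = x$cutpoint, n = x$n, n_events = x$n_events,
    hr = x$hr$hr, hr_conf_low = x$hr$conf_low, hr_conf_high = x$hr$conf_high,
    logrank_chisq = x$logrank$chisq, logrank_p = x$logrank$p_value
  )
}

#' Tidy a ROC result into curve points
#'
#' @param x A `cerna_roc` from [roc_auc()].
#' @param ... Unused.
#' @return Tibble of (threshold, fpr, tpr) points.
#' @method tidy cerna_roc
#' @export
tidy.cerna_roc <- function(x, ...) x$points

#' One-row summary of a ROC result
#'
#' @param x A `cerna_roc`.
#' @param ... Unused.
#' @return Tibble with AUC, its p value versus 0.5, the Youden-optimal
#'   threshold and the operating-point metrics.
#' @method glance cerna_roc
#' @export
glance.cerna_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, p_value = x$p_value, threshold = x$threshold,
    sn = x$sn, sp = x$sp, ac = x$ac,
    n_case = x$n_case, n_control = x$n_control, flipped = x$flipped
  )
}
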