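#' Volcano plot of a differential-expression table
#'
#' log2 fold change against -log10(FDR), colored by the direction call.
#' Infinite -log10(FDR) values (the noiseless limit) are capped at the
#' largest finite value plus one so every feature is drawn.
#'
#' @param object A `de_table` from [call_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, ...) {
  v <- volcano_table(object)
  cap <- max(v$neg_log10_fdr[is.finite(v$neg_log10_fdr)], 0) + 1
  v$neg_log10_fdr <- pmin(v$neg_log10_fdr, cap)
  th <- attr(object, "thresholds")
  ggplot2::ggplot(v, ggplot2::aes(.data$log2fc, .data$neg_log10_fdr,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = th$neg_log_fdr_min, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th$abs_log2fc_min,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(up = "#2e7d32", down = "#c62828", ns = "grey30")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10(FDR)",
                  colour = NULL,
                  title = paste0(object$rna_class[1], " differential expression")) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a survival fit
#'
#' @param object A `cerna_survfit` from [survival_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cerna_survfit
#' @export
autoplot.cerna_survfit <- function(object, ...) {
  steps <- object$km |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")]
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability", colour = object$gene,
      title = sprintf("%s: HR = %.2f, log-rank p = %.3g",
                      object$gene, object$hr$hr, object$logrank$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `cerna_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cerna_roc
#' @export
autoplot.cerna_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "false positive rate (1 - specificity)",
      y = "sensitivity",
      title = sprintf("AUC = %.3f (SN %.2f, SP %.2f, AC %.2f)",
                      object$auc, object$sn, object$sp, object$ac)
    ) +
    ggplot2::theme_minimal()
}

#' Sample-correlation clustergram plot
#'
#' Tile plot of the Pearson sample-sample correlation matrix with rows
#' and columns in the average-linkage leaf order.
#'
#' @param expr Wide expression tibble (`feature_id` + sample columns).
#' @return A ggplot object.
#' @export
plot_clustergram <- function(expr) {
  cg <- correlation_clustergram(expr)
  long <- tibble::as_tibble(cg$correlation, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r") |>
    dplyr::mutate(
      sample_a = factor(.data$sample_a, levels = cg$order),
      sample_b = factor(.data$sample_b, levels = cg$order)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#c62828", mid = "white",
                                  high = "#1565c0", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
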