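#' Log2 fold change between two group means
#'
#' @param mean_case,mean_control Group means, on the scale named by
#'   `scale`: `"log2"` means are log2 intensities and the fold change is
#'   their difference; `"linear"` means are raw intensities (must be
#'   positive) and the fold change is `log2(case/control)`.
#' @param scale `"log2"` (default, microarray convention) or `"linear"`.
#' @return Numeric log2 fold change (vectorized).
#' @examples
#' log2_fold_change(8, 2, scale = "linear") # 2
#' log2_fold_change(5.5, 7.5)               # -2
#' @export
log2_fold_change <- function(mean_case, mean_control, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (scale == "linear") {
    if (any(mean_case <= 0) || any(mean_control <= 0)) {
      abort("linear-scale means must be positive.")
    }
    log2(mean_case / mean_control)
  } else {
    mean_case - mean_control
  }
}

#' Welch's two-sample t test
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. Degenerate inputs follow explicit
#' conventions rather than erroring: if both groups have zero variance and
#' equal means, t = 0 and p = 1; if the means differ with zero variance in
#' both groups, p = 0 and the result is flagged `degenerate` (the
#' noiseless limit, where any difference is infinitely significant).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble with `t`, `df`, `p_value`, `degenerate`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) {
      return(tibble::tibble(t = 0, df = na + nb - 2, p_value = 1, degenerate = TRUE))
    }
    return(tibble::tibble(t = sign(ma - mb) * Inf, df = na + nb - 2,
                          p_value = 0, degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation;
#' output order matches input order and values are capped at 1.
#'
#' @param p_values Numeric vector of p values in [0, 1].
#' @return Vector of q values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  assert_prob(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Differential-expression thresholds
#'
#' The gates used to call a feature differentially expressed: a raw
#' p-value ceiling, a minimum on -log10(FDR), and a minimum absolute log2
#' fold change. `rule` selects whether the significance gate is the union
#' (`"p_or_fdr"`, the profile-wide convention: p <= 0.05 OR -log FDR >=
#' 2.0) or the intersection of the two. The fold-change gate defaults to
#' |log2FC| >= 1, i.e. a linear two-fold change.
#'
#' @param p_max Raw p-value ceiling (default 0.05).
#' @param neg_log_fdr_min Minimum -log10(FDR) (default 2.0, i.e. q <= 0.01).
#' @param abs_log2fc_min Minimum |log2FC| (default 1.0).
#' @param rule `"p_or_fdr"` (default) or `"p_and_fdr"`.
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(p_max = 0.05, neg_log_fdr_min = 2.0,
                          abs_log2fc_min = 1.0,
                          rule = c("p_or_fdr", "p_and_fdr")) {
  rule <- match.arg(rule)
  if (p_max <= 0 || neg_log_fdr_min <= 0 || abs_log2fc_min <= 0) {
    abort("all thresholds must be > 0.")
  }
  structure(list(p_max = p_max, neg_log_fdr_min = neg_log_fdr_min,
                 abs_log2fc_min = abs_log2fc_min, rule = rule),
            class = "de_thresholds")
}

#' Classify DE direction from precomputed statistics
#'
#' Applies the significance rule and fold-change gate of a
#' [de_thresholds()] object to per-feature statistics, yielding the
#' up/down/ns call. Useful when the fold changes and p/FDR values come
#' from an external DE table rather than from [call_de()].
#'
#' @param log2fc,p_value,fdr Numeric vectors (same length).
#' @param thresholds A [de_thresholds()] object.
#' @return List with `direction` (up/down/ns) and `gate` (which
#'   significance gate passed: p/fdr/both/none).
#' @export
classify_direction <- function(log2fc, p_value, fdr, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  p_pass <- p_value <= thresholds$p_max
  fdr_pass <- -log10(fdr) >= thresholds$neg_log_fdr_min
  sig <- if (thresholds$rule == "p_or_fdr") p_pass | fdr_pass else p_pass & fdr_pass
  fc_pass <- abs(log2fc) >= thresholds$abs_log2fc_min
  list(
    direction = dplyr::case_when(
      sig & fc_pass & log2fc > 0 ~ "up",
      sig & fc_pass & log2fc < 0 ~ "down",
      .default = "ns"
    ),
    gate = dplyr::case_when(
      p_pass & fdr_pass ~ "both",
      p_pass ~ "p",
      fdr_pass ~ "fdr",
      .default = "none"
    )
  )
}

#' Call differential expression on one expression matrix
#'
#' Per feature: group means, log2 fold change (inputs are log2
#' intensities), signed linear fold change, Welch t test, BH-FDR across
#' the whole profile, and a direction call. A feature is `up` when it
#' passes the significance rule of `thresholds`, has log2FC > 0 and
#' |log2FC| at or above the fold-change gate; `down` is symmetric; all
#' other features are `ns`. The gate each significant feature passed
#' (p, fdr or both) is recorded.
#'
#' @param expr Wide expression tibble: `feature_id` column, then one
#'   column per sample (log2 intensities).
#' @param groups Tibble with `sample_id` and `group` (levels control/case;
#'   the first level in sorted-unique order that matches "control" is the
#'   reference, otherwise supply a factor).
#' @param rna_class Label stored per record: `"lncRNA"`, `"miRNA"` or
#'   `"mRNA"`.
#' @param thresholds A [de_thresholds()] object.
#' @param na_policy `"drop"` removes features with any missing value
#'   (logged via a message); `"pairwise"` computes each feature on its
#'   complete observations.
#' @return A `de_table` tibble, one row per feature, with columns
#'   `feature_id`, `rna_class`, `mean_control`, `mean_case`, `log2fc`,
#'   `fold_change`, `t`, `df`, `p_value`, `fdr`, `neg_log_fdr`,
#'   `direction`, `gate`, `degenerate`.
#' @export
call_de <- function(expr, groups, rna_class = c("mRNA", "lncRNA", "miRNA"),
                    thresholds = de_thresholds(),
                    na_policy = c("drop", "pairwise")) {
  rna_class <- match.arg(rna_class)
  na_policy <- match.arg(na_policy)
  stopifnot(inherits(thresholds, "de_thresholds"))
  mat <- expr_to_matrix(expr)
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  groups <- groups[match(colnames(mat), groups$sample_id), ]
  if (anyNA(groups$group)) abort("every expression column needs a group label.")
  is_control <- groups$group %in% c("control", "normal", "Control")
  if (!any(is_control) || all(is_control)) {
    abort("`groups` must contain both a control/normal group and a case group.")
  }
  if (sum(is_control) < 2 || sum(!is_control) < 2) {
    abort("need at least 2 samples per group.")
  }

  if (na_policy == "drop" && anyNA(mat)) {
    bad <- rowSums(is.na(mat)) > 0
    message(sprintf("dropping %d feature(s) with missing values.", sum(bad)))
    mat <- mat[!bad, , drop = FALSE]
  }

  stats_tbl <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    a <- mat[i, !is_control]  # case
    b <- mat[i, is_control]   # control
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    welch_t_test(a, b)
  })

  mean_case <- unname(rowMeans(mat[, !is_control, drop = FALSE], na.rm = TRUE))
  mean_control <- unname(rowMeans(mat[, is_control, drop = FALSE], na.rm = TRUE))
  log2fc <- mean_case - mean_control
  fdr <- bh_fdr(stats_tbl$p_value)

  th <- thresholds
  neg_log_fdr <- -log10(fdr)
  calls <- classify_direction(log2fc, stats_tbl$p_value, fdr, th)

  out <- tibble::tibble(
    feature_id = rownames(mat),
    rna_class = rna_class,
    mean_control = mean_control,
    mean_case = mean_case,
    log2fc = log2fc,
    fold_change = sign(log2fc) * 2^abs(log2fc),
    t = stats_tbl$t, df = stats_tbl$df,
    p_value = stats_tbl$p_value, fdr = fdr, neg_log_fdr = neg_log_fdr,
    direction = calls$direction,
    gate = calls$gate,
    degenerate = stats_tbl$degenerate
  )
  attr(out, "thresholds") <- th
  class(out) <- c("de_table", class(out))
  out
}

#' Count up/down/total differentially expressed features
#'
#' @param de A `de_table` from [call_de()].
#' @return One-row tibble: `rna_class`, `n_features`, `n_up`, `n_down`,
#'   `n_de`.
#' @export
de_counts <- function(de) {
  tibble::tibble(
    rna_class = de$rna_class[1] %||% NA_character_,
    n_features = nrow(de),
    n_up = sum(de$direction == "up"),
    n_down = sum(de$direction == "down"),
    n_de = sum(de$direction != "ns")
  )
}

#' Volcano-plot export table
#'
#' One row per feature with the two volcano coordinates and the color
#' class matching the [call_de()] direction call. Infinite -log10(FDR)
#' (the noiseless limit) is preserved; cap it at plotting time if needed.
#'
#' @param de A `de_table`.
#' @return Tibble `feature_id`, `log2fc`, `neg_log10_fdr`, `class`.
#' @export
volcano_table <- function(de) {
  stopifnot(inherits(de, "de_table"))
  tibble::tibble(
    feature_id = de$feature_id,
    log2fc = de$log2fc,
    neg_log10_fdr = de$neg_log_fdr,
    class = de$direction
  )
}

#' Sample-sample correlation matrix with hierarchical leaf order
#'
#' Pearson correlation between samples and the average-linkage
#' hierarchical clustering of 1 - r, as drawn in an expression
#' clustergram. Samples are pre-sorted lexicographically so the leaf
#' order is deterministic under ties.
#'
#' @param expr Wide expression tibble (`feature_id` + sample columns).
#' @return List with `correlation` (symmetric matrix, unit diagonal),
#'   `order` (leaf order, sample names), and `hclust` (the tree).
#' @export
correlation_clustergram <- function(expr) {
  mat <- expr_to_matrix(expr)
  if (ncol(mat) < 2) abort("need at least 2 samples.")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance sample(s): %s — correlation undefined.",
                  paste(colnames(mat)[sds == 0], collapse = ", ")))
  }
  r <- cor(mat, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, order = colnames(mat)[hc$order], hclust = hc)
}
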