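#' Dichotomize expression into high/low groups
#'
#' Median split by default (values at or below the cutpoint, including
#' ties with it, go to `low`); the quantile method splits at an arbitrary
#' quantile of the observed values.
#'
#' @param values Numeric expression values, length >= 2.
#' @param method `"median"` (default) or `"quantile"`.
#' @param q Quantile for the quantile method (default 0.5).
#' @return Factor with levels low/high and attribute `cutpoint`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))
#' @export
dichotomize <- function(values, method = c("median", "quantile"), q = 0.5) {
  method <- match.arg(method)
  if (length(values) < 2) abort("need at least 2 subjects.")
  if (length(unique(values)) == 1) {
    abort("constant expression: no high/low split possible.")
  }
  cutpoint <- if (method == "median") median(values) else quantile(values, q, names = FALSE)
  grp <- factor(ifelse(values > cutpoint, "high", "low"), levels = c("low", "high"))
  attr(grp, "cutpoint") <- cutpoint
  grp
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival curve(s) via [survival::survfit()]; censored subjects leave
#' the risk set without a drop in the curve.
#'
#' @param records Tibble with `time`, `event` (1 = death, 0 = censored)
#'   and optionally `group`.
#' @return Tidy step tibble: `group` (if present), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) abort("negative survival time.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  has_group <- "group" %in% names(records)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  tibble::tibble(
    group = if (has_group) sub("^group=", "", as.character(s$strata)) else "all",
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv
  )
}

logrank_oe <- function(records) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(obs = sd$obs, exp = sd$exp, var = sd$var, chisq = sd$chisq,
       groups = sub("^group=", "", names(sd$n)))
}

#' Two-group log-rank test
#'
#' Observed-versus-expected events over the pooled event times; the
#' chi-square statistic has 1 degree of freedom. With no events at all
#' the test is vacuous: chi-square 0, p = 1 (with a warning).
#'
#' @param records Tibble with `time`, `event`, `group` (two levels).
#' @return One-row tibble: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (length(unique(records$group)) != 2) abort("`group` must have two levels.")
  if (sum(records$event) == 0) {
    warn("no events in either group: log-rank test is vacuous.")
    return(tibble::tibble(chisq = 0, df = 1L, p_value = 1))
  }
  oe <- logrank_oe(records)
  tibble::tibble(chisq = oe$chisq, df = 1L,
                 p_value = pchisq(oe$chisq, df = 1, lower.tail = FALSE))
}

#' Mantel-Haenszel hazard ratio between two groups
#'
#' The observed/expected estimate from the log-rank tabulation,
#' HR = (O1/E1)/(O2/E2) with the first level of `group` in the
#' numerator, and the 95% confidence interval
#' exp(log HR +/- 1.96 sqrt(1/E1 + 1/E2)).
#'
#' @param records Tibble with `time`, `event`, `group` (two levels; the
#'   factor's first level — or sorted-first value — is the numerator).
#' @return One-row tibble: `hr`, `conf_low`, `conf_high`, `numerator`.
#' @export
hazard_ratio <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (length(unique(records$group)) != 2) abort("`group` must have two levels.")
  if (sum(records$event) == 0) {
    warn("no events: hazard ratio undefined.")
    return(tibble::tibble(hr = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, numerator = NA_character_))
  }
  oe <- logrank_oe(records)
  if (any(oe$exp == 0)) {
    warn("zero expected events in a group: hazard ratio undefined.")
    return(tibble::tibble(hr = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, numerator = oe$groups[1]))
  }
  log_hr <- log((oe$obs[1] / oe$exp[1]) / (oe$obs[2] / oe$exp[2]))
  se <- sqrt(1 / oe$exp[1] + 1 / oe$exp[2])
  tibble::tibble(
    hr = exp(log_hr),
    conf_low = exp(log_hr - 1.96 * se),
    conf_high = exp(log_hr + 1.96 * se),
    numerator = oe$groups[1]
  )
}

#' Survival analysis of one gene in a clinical cohort
#'
#' Dichotomizes the gene's expression into high/low groups, estimates the
#' Kaplan-Meier curves, the log-rank test and the Mantel-Haenszel hazard
#' ratio of high versus low expression.
#'
#' @param clinical Clinical tibble with `time`, `event` and one column
#'   per gene (e.g. from [simulate_clinical()]).
#' @param gene Name of the gene column.
#' @param method,q Passed to [dichotomize()].
#' @return A `cerna_survfit` object; use [tidy()] for the KM steps,
#'   [glance()] for the test summary, [autoplot()] for the curves.
#' @export
survival_fit <- function(clinical, gene, method = "median", q = 0.5) {
  clinical <- tibble::as_tibble(clinical)
  if (!gene %in% names(clinical)) {
    abort(sprintf("gene '%s' is not a column of the clinical table.", gene))
  }
  grp <- dichotomize(clinical[[gene]], method = method, q = q)
  records <- tibble::tibble(
    time = clinical$time, event = clinical$event,
    group = factor(grp, levels = c("high", "low"))
  )
  structure(
    list(
      gene = gene,
      cutpoint = attr(grp, "cutpoint"),
      km = km_estimate(records),
      logrank = logrank_test(records),
      hr = hazard_ratio(records),
      n = nrow(records), n_events = sum(records$event)
    ),
    class = "cerna_survfit"
  )
}

#' @export
print.cerna_survfit <- function(x, ...) {
  cat(sprintf(
    "Survival fit for %s (n = %d, events = %d, cutpoint = %.3g)\n",
    x$gene, x$n, x$n_events, x$cutpoint
  ))
  cat(sprintf("  HR (high vs low) = %.3f [%.3f, %.3f]\n",
              x$hr$hr, x$hr$conf_low, x$hr$conf_high))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.3g\n",
              x$logrank$chisq, x$logrank$p_value))
  invisible(x)
}

# ROC --------------------------------------------------------------------

#' Empirical ROC curve, AUC and operating-point metrics
#'
#' The ROC sweeps every observed score as a threshold (rule: predict case
#' when score >= threshold, by default treating high scores as
#' case-like). AUC is computed as the Mann-Whitney probability that a
#' random case outscores a random control, with ties counted one half —
#' identical to the trapezoidal area under the empirical curve. The
#' operating threshold maximizes Youden's J = SN + SP - 1 (ties broken by
#' the lower threshold); sensitivity, specificity and raw accuracy are
#' reported there. The p value tests AUC = 0.5 via the tie-corrected
#' normal approximation of the Mann-Whitney statistic.
#'
#' @param scores Numeric scores (e.g. expression), higher = more
#'   case-like under `direction = "case_high"`.
#' @param labels Class labels; `case` names the positive class value.
#' @param case Value of `labels` treated as the positive class.
#' @param direction `"case_high"` (default) keeps the stated orientation;
#'   `"auto"` flips the scores when the raw AUC is below 0.5, as clinical
#'   ROC software does, and records the flip.
#' @return A `cerna_roc` object; [tidy()] gives the ROC points,
#'   [glance()] the summary metrics, [autoplot()] the curve.
#' @examples
#' roc_auc(c(3, 2, 1, 2.5), c("tumor", "tumor", "normal", "normal"))
#' @export
roc_auc <- function(scores, labels, case = "tumor",
                    direction = c("case_high", "auto")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  is_case <- labels == case
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("both classes must be present.")

  auc_of <- function(s) {
    r <- rank(s)  # midranks: ties count one half
    (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  flipped <- FALSE
  if (direction == "auto" && auc_of(scores) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  auc <- auc_of(scores)

  thresholds <- sort(unique(scores))
  pts <- purrr::map_dfr(thresholds, function(th) {
    pred <- scores >= th
    tibble::tibble(
      threshold = th,
      tpr = sum(pred & is_case) / n1,
      fpr = sum(pred & !is_case) / n0
    )
  })
  pts <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, tpr = 0, fpr = 0),
    dplyr::arrange(pts, .data$fpr, .data$tpr),
    tibble::tibble(threshold = -Inf, tpr = 1, fpr = 1)
  ) |> dplyr::distinct()

  j <- pts$tpr - pts$fpr
  finite <- is.finite(pts$threshold)
  best_j <- max(j[finite])
  best <- pts[finite & j == best_j, ]
  best <- best[which.min(best$threshold), ]
  pred <- scores >= best$threshold
  sn <- sum(pred & is_case) / n1
  sp <- sum(!pred & !is_case) / n0
  ac <- (sum(pred & is_case) + sum(!pred & !is_case)) / length(scores)

  # normal approximation of the Mann-Whitney U test with tie correction
  n <- n1 + n0
  u <- auc * n1 * n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  var_u <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p_value <- if (var_u == 0) 1 else 2 * pnorm(-abs(u - n1 * n0 / 2) / sqrt(var_u))

  structure(
    list(points = pts, auc = auc, threshold = best$threshold,
         sn = sn, sp = sp, ac = ac, p_value = p_value,
         n_case = n1, n_control = n0, flipped = flipped),
    class = "cerna_roc"
  )
}

#' @export
print.cerna_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (p vs 0.5 = %.3g), threshold = %.3g%s\n  SN = %.3f, SP = %.3f, AC = %.3f (cases = %d, controls = %d)\n",
    x$auc, x$p_value, x$threshold, if (x$flipped) " [score flipped]" else "",
    x$sn, x$sp, x$ac, x$n_case, x$n_control
  ))
  invisible(x)
}

#' Prognostic and diagnostic report for one ceRNA axis
#'
#' For each of the three axis components, dichotomizes its expression,
#' runs the Kaplan-Meier/log-rank/hazard-ratio survival analysis, and
#' evaluates the component as a tumor-versus-normal diagnostic marker by
#' ROC. No pooling across components is done: the module summary is the
#' component-wise table, as clinical validation of a ceRNA module
#' inspects each collaborator separately.
#'
#' @param axis Either a one-row `cerna_axes` tibble or a character vector
#'   of the three component IDs (lncRNA, miRNA, mRNA).
#' @param clinical Clinical tibble (`time`, `event`, `label`, gene
#'   columns), e.g. from [simulate_clinical()].
#' @param case Positive-class value of `label`.
#' @param method,q Dichotomization rule, as in [dichotomize()].
#' @param roc_direction Passed to [roc_auc()]; the default `"auto"`
#'   orients each marker so AUC >= 0.5, as clinical ROC reports do.
#' @return Tibble, one row per component: `component`, `role`, `hr`,
#'   `hr_conf_low`, `hr_conf_high`, `logrank_p`, `auc`, `auc_p`, `sn`,
#'   `sp`, `ac`.
#' @export
module_report <- function(axis, clinical, case = "tumor",
                          method = "median", q = 0.5,
                          roc_direction = "auto") {
  if (inherits(axis, "cerna_axes") || is.data.frame(axis)) {
    stopifnot(nrow(axis) == 1)
    ids <- c(axis$lncrna_id, axis$mirna_id, axis$mrna_id)
  } else {
    stopifnot(is.character(axis), length(axis) == 3)
    ids <- axis
  }
  clinical <- tibble::as_tibble(clinical)
  missing <- setdiff(ids, names(clinical))
  if (length(missing) > 0) {
    abort(sprintf("component(s) absent from the clinical table: %s",
                  paste(missing, collapse = ", ")))
  }
  roles <- c("lncRNA", "miRNA", "mRNA")
  purrr::map2_dfr(ids, roles, function(id, role) {
    sf <- survival_fit(clinical, id, method = method, q = q)
    roc <- roc_auc(clinical[[id]], clinical$label, case = case,
                   direction = roc_direction)
    tibble::tibble(
      component = id, role = role,
      hr = sf$hr$hr, hr_conf_low = sf$hr$conf_low,
      hr_conf_high = sf$hr$conf_high,
      logrank_p = sf$logrank$p_value,
      auc = roc$auc, auc_p = roc$p_value,
      sn = roc$sn, sp = roc$sp, ac = roc$ac
    )
  })
}
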