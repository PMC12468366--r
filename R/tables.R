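#' Group comparison table for flow metrics
#'
#' Summarizes each metric as mean and SD per group and compares the two
#' groups with the Mann-Whitney test — the shape of the published
#' group-comparison tables.
#'
#' @param data Subject-level tibble with a group column and one column per
#'   metric (e.g. from [simulate_metric_cohort()] or stacked
#'   [run_subject()] results).
#' @param group Name of the group column (exactly two groups).
#' @param metrics Metric columns to compare; defaults to every canonical
#'   metric field present in `data`.
#' @param alpha Significance level used for the `significant` flag.
#' @return A tibble with one row per metric: `group_a`, `mean_a`, `sd_a`,
#'   `group_b`, `mean_b`, `sd_b`, `u_statistic`, `p_value`, `significant`.
#' @export
cohort_compare <- function(data, group = "group", metrics = NULL,
                           alpha = 0.05) {
  metrics <- metrics %||% intersect(metric_fields(), names(data))
  if (length(metrics) == 0) {
    abort("No metric columns found in `data`.",
          class = "csfflow_config_error")
  }
  g <- factor(data[[group]])
  lev <- levels(droplevels(g))
  if (length(lev) != 2) {
    abort("`cohort_compare()` needs exactly two groups.",
          class = "csfflow_config_error")
  }
  rows <- map(metrics, function(mt) {
    va <- data[[mt]][g == lev[1]]
    vb <- data[[mt]][g == lev[2]]
    mw <- mann_whitney(va, vb)
    tibble(
      metric = mt,
      group_a = lev[1], n_a = length(va), mean_a = mean(va), sd_a = sd(va),
      group_b = lev[2], n_b = length(vb), mean_b = mean(vb), sd_b = sd(vb),
      u_statistic = mw$U, p_value = mw$p, significant = mw$p < alpha
    )
  })
  bind_rows(rows)
}

#' ROC table for flow metrics
#'
#' Runs [roc()] per metric against a two-group label and reports the AUC,
#' Youden-optimal cutoff and its sensitivity/specificity in percent — the
#' shape of the published diagnostic-performance tables.
#'
#' @inheritParams cohort_compare
#' @param positive Group label treated as the positive class; defaults to
#'   the second factor level of the group column.
#' @return A tibble with one row per metric: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `direction`.
#' @export
cohort_roc <- function(data, group = "group", positive = NULL,
                       metrics = NULL) {
  metrics <- metrics %||% intersect(metric_fields(), names(data))
  if (length(metrics) == 0) {
    abort("No metric columns found in `data`.",
          class = "csfflow_config_error")
  }
  g <- factor(data[[group]])
  lev <- levels(droplevels(g))
  if (length(lev) != 2) {
    abort("`cohort_roc()` needs exactly two groups.",
          class = "csfflow_config_error")
  }
  positive <- positive %||% lev[2]
  rows <- map(metrics, function(mt) {
    r <- roc(data[[mt]], as.character(g), positive = positive)
    tibble(metric = mt, auc = r$auc, cutoff = r$cutoff,
           sensitivity = r$sensitivity, specificity = r$specificity,
           direction = r$positive_direction)
  })
  bind_rows(rows)
}
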