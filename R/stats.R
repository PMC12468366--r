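#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups with midrank ties. The exact
#' null distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with continuity and
#' tie correction.
#'
#' @param a,b Numeric vectors (each nonempty).
#' @return A list with `U` (the U statistic of `a` relative to `b`) and `p`
#'   (two-sided).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must be nonempty.", class = "csfflow_config_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by the point-probability method (tables as or less probable
#' than the observed one).
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(10, 9, 2, 4), nrow = 2)) # ~0.64
#' @export
fisher_exact <- function(table) {
  check_counts_2x2(table)
  fisher.test(table)$p.value
}

#' Chi-square test on a contingency table
#'
#' @param table A matrix of non-negative integer counts with nonzero margins.
#' @param correct Apply Yates continuity correction for 2x2 tables.
#' @return A list with `statistic` (X-squared) and `p`.
#' @export
chi_square <- function(table, correct = TRUE) {
  check_counts_2x2(table, square_only = FALSE)
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

check_counts_2x2 <- function(table, square_only = TRUE) {
  if (!is.matrix(table) || any(table < 0) ||
      any(table != round(table)) ||
      (square_only && !all(dim(table) == 2))) {
    abort("Expected a matrix of non-negative integer counts (2x2).",
          class = "csfflow_config_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate table: a row or column margin is zero.",
          class = "csfflow_degenerate_error")
  }
  invisible(table)
}

# Empirical AUC for "higher value => positive" via the rank (Mann-Whitney)
# identity; midranks give ties a half count.
empirical_auc <- function(values, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(values)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC of a single metric against a binary label. The AUC is
#' computed through the Mann-Whitney identity (ties count one half). The
#' orientation (`higher-is-positive` vs `lower-is-positive`) is chosen
#' automatically so that AUC >= 0.5, and recorded. The reported cutoff
#' maximizes the Youden index `J = sensitivity + specificity - 1` over
#' midpoints between adjacent observed values (smallest cutoff on ties),
#' which is deterministic and threshold-stable.
#'
#' @param values Per-subject metric values.
#' @param labels Binary labels (logical, 0/1, or a two-level factor).
#' @param positive Which label is the positive class; defaults to `TRUE`,
#'   `1`, or the second factor level.
#' @return A `roc_result` with `auc`, `cutoff`, `sensitivity` and
#'   `specificity` (percent), `positive_direction`, the full ROC `curve`
#'   (tibble of threshold/sensitivity/specificity), and class counts.
#' @examples
#' roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc <- function(values, labels, positive = NULL) {
  if (length(values) != length(labels)) {
    abort("`values` and `labels` must have equal length.",
          class = "csfflow_config_error")
  }
  if (is.factor(labels) || is.character(labels)) {
    lev <- if (is.factor(labels)) levels(droplevels(factor(labels))) else
      sort(unique(labels))
    if (length(lev) != 2) {
      abort("`labels` must have exactly two classes.",
            class = "csfflow_config_error")
    }
    positive <- positive %||% lev[2]
    is_pos <- labels == positive
  } else {
    positive <- positive %||% max(labels)
    is_pos <- labels == positive
  }
  if (!any(is_pos) || all(is_pos)) {
    abort("Both classes must be present.", class = "csfflow_config_error")
  }

  auc_hi <- empirical_auc(values, is_pos)
  higher_positive <- auc_hi >= 0.5
  auc <- if (higher_positive) auc_hi else 1 - auc_hi

  s <- sort(unique(values))
  thr <- if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2 else s
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- if (higher_positive) values >= thr[i] else values <= thr[i]
    sens[i] <- mean(pred[is_pos])
    spec[i] <- mean(!pred[!is_pos])
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]

  curve <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  structure(
    list(
      auc = auc, cutoff = thr[best],
      sensitivity = 100 * sens[best], specificity = 100 * spec[best],
      positive_direction = if (higher_positive) "higher-is-positive" else
        "lower-is-positive",
      positive_label = positive, curve = curve,
      n_pos = sum(is_pos), n_neg = sum(!is_pos)
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f | cutoff %.4f (%s) | sens %.1f%% | spec %.1f%% | n=%d/%d\n",
    x$auc, x$cutoff, x$positive_direction, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Closed-form AUC of a binormal separation
#'
#' For a positive class `Normal(mu_pos, sd_pos)` against a negative class
#' `Normal(mu_neg, sd_neg)`, the population AUC is
#' `Phi((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Serves as the
#' analytic oracle for cohort simulations.
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg Group means and SDs (`sd >= 0`, not
#'   both zero unless means differ).
#' @return AUC in `[0, 1]`.
#' @examples
#' binormal_auc(1.87, 0.52, 1.28, 0.50) # ~0.793
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (sd_pos < 0 || sd_neg < 0) {
    abort("SDs must be non-negative.", class = "csfflow_config_error")
  }
  den <- sqrt(sd_pos^2 + sd_neg^2)
  if (den == 0) {
    # Degenerate limit: point masses.
    return(0.5 + 0.5 * sign(mu_pos - mu_neg))
  }
  pnorm((mu_pos - mu_neg) / den)
}

#' Normality check (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with estimated mean and
#' SD. For n >= 5 the Lilliefors correction accounts for the parameter
#' estimation; smaller samples fall back to the plain KS test (noted in the
#' method string). A constant input is degenerate: the p-value is reported
#' below the machine floor with a warning.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return A list with `statistic`, `p` and `method`.
#' @export
normality_check <- function(values) {
  if (length(values) < 3) {
    abort("Need at least 3 values.", class = "csfflow_config_error")
  }
  if (sd(values) == 0) {
    warn("Constant input: normality is degenerate; p reported below machine floor.")
    return(list(statistic = NA_real_, p = .Machine$double.xmin,
                method = "degenerate (constant input)"))
  }
  if (length(values) >= 5) {
    ht <- nortest::lillie.test(values)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "Lilliefors-corrected Kolmogorov-Smirnov")
  } else {
    ht <- suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))
    )
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "Kolmogorov-Smirnov (estimated parameters, uncorrected)")
  }
}
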