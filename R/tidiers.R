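#' Tidy a ROC result
#'
#' @param x A `roc_result` from [roc()].
#' @param ... Unused.
#' @return A one-row tibble with `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `direction`, `n_pos`, `n_neg`.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, cutoff = x$cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, direction = x$positive_direction,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) tidy.roc_result(x)

#' Tidy a subject-level pipeline result
#'
#' @param x A `subject_result` from [run_subject()].
#' @param ... Unused.
#' @return A long tibble of the combined metrics with `metric`, `value`,
#'   `unit`.
#' @export
tidy.subject_result <- function(x, ...) tidy(x$metrics)

#' One-row summary of a subject-level pipeline result
#'
#' @param x A `subject_result`.
#' @param ... Unused.
#' @return A one-row tibble: the ten combined metrics plus
#'   `n_acquisitions` and `config_hash`.
#' @export
glance.subject_result <- function(x, ...) {
  mutate(as_tibble(x$metrics), n_acquisitions = x$n_acquisitions,
         config_hash = x$config_hash)
}

#' Tidy a cohort result
#'
#' @param x A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return The group-comparison tibble joined with the ROC tibble, one row
#'   per metric.
#' @export
tidy.cohort_result <- function(x, ...) {
  left_join(x$comparison, x$roc, by = "metric")
}

#' @rdname tidy.cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  tibble(
    n_groups = length(x$n), n_subjects = sum(x$n),
    n_metrics = nrow(x$comparison),
    n_significant = sum(x$comparison$significant),
    max_auc = max(x$roc$auc)
  )
}
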