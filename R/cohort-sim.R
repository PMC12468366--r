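#' Published reference cohort summaries for C2 CSF flow metrics
#'
#' Group-level mean and standard deviation of the nine tabulated CSF flow
#' metrics, as reported for (a) the baseline contrast between spontaneous
#' intracranial hypotension (SIH) patients and healthy volunteers (HV), and
#' (b) the post-first-epidural-blood-patch contrast between patients who
#' recovered after one patch (EBP_success) and those needing repeat patches
#' (EBP_failure). These summaries parameterize [simulate_metric_cohort()].
#'
#' @return A tibble with columns `cohort` (`"baseline"` or `"post_ebp"`),
#'   `group`, `n`, `metric`, `mean`, `sd`. Flow units are mL/s for mean/peak
#'   metrics and mL/cycle for per-cycle totals and stroke volume.
#' @examples
#' dplyr::filter(csf_reference_cohorts(), metric == "upward_peak_flow")
#' @export
csf_reference_cohorts <- function() {
  m9 <- metric_fields()[1:9]
  grp <- function(cohort, group, n, means, sds) {
    tibble(cohort = cohort, group = group, n = n, metric = m9,
           mean = means, sd = sds)
  }
  bind_rows(
    grp("baseline", "SIH", 31,
        c(0.76, 1.01, 1.77, 1.28, 1.76, 3.04, 14.32, 13.22, 27.54),
        c(0.31, 0.43, 0.72, 0.50, 0.77, 1.26, 5.59, 5.65, 11.03)),
    grp("baseline", "HV", 26,
        c(1.18, 1.60, 2.78, 1.87, 2.96, 4.83, 22.24, 20.74, 42.98),
        c(0.34, 0.54, 0.84, 0.52, 0.92, 1.39, 6.55, 6.66, 12.86)),
    grp("post_ebp", "EBP_failure", 12,
        c(0.691, 0.84, 1.53, 1.13, 1.45, 2.58, 12.47, 14.58, 24.04),
        c(0.14, 0.24, 0.36, 0.24, 0.42, 0.61, 2.64, 2.95, 5.45)),
    grp("post_ebp", "EBP_success", 13,
        c(1.26, 1.81, 3.07, 2.00, 2.98, 4.98, 24.26, 22.92, 47.17),
        c(0.23, 0.46, 0.65, 0.34, 0.64, 0.95, 5.13, 4.35, 9.16))
  )
}

#' Simulate a subject-level metric cohort from group summaries
#'
#' Draws each subject's metrics independently from `Normal(mean, sd)`,
#' truncated at zero by default (flow magnitudes are non-negative physical
#' quantities; truncation avoids nonsense negatives at the published SDs).
#' Truncated draws use the inverse-CDF method so a fixed seed gives
#' bit-identical cohorts.
#'
#' @param spec A data frame with columns `group`, `n`, `metric`, `mean`,
#'   `sd` — one row per group x metric, `n` constant within group (see
#'   [csf_reference_cohorts()] for the canonical shape).
#' @param seed Optional integer seed.
#' @param truncate If `TRUE` (default), draws are truncated at 0.
#' @return A tibble with `subject_id`, `group` (factor in order of first
#'   appearance) and one column per metric.
#' @examples
#' spec <- dplyr::filter(csf_reference_cohorts(), cohort == "baseline",
#'                       metric == "upward_peak_flow")
#' simulate_metric_cohort(spec, seed = 1)
#' @export
simulate_metric_cohort <- function(spec, seed = NULL, truncate = TRUE) {
  need <- c("group", "n", "metric", "mean", "sd")
  if (!all(need %in% names(spec))) {
    abort(sprintf("`spec` must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "csfflow_config_error")
  }
  if (any(spec$sd < 0)) {
    abort("Group SDs must be >= 0.", class = "csfflow_config_error")
  }
  groups <- unique(spec$group)
  sizes <- vapply(groups, function(g) {
    ns <- unique(spec$n[spec$group == g])
    if (length(ns) != 1) {
      abort(sprintf("Group `%s` has inconsistent `n`.", g),
            class = "csfflow_config_error")
    }
    as.integer(ns)
  }, integer(1))
  if (any(sizes < 2)) {
    abort("Each group needs n >= 2 subjects.", class = "csfflow_config_error")
  }
  metrics <- unique(spec$metric)
  if (!is.null(seed)) set.seed(seed)

  draw <- function(n, m, s) {
    if (s == 0) return(rep(m, n))
    if (!truncate) return(rnorm(n, m, s))
    lo <- pnorm(0, m, s)
    qnorm(runif(n, lo, 1), m, s)
  }

  out <- map(seq_along(groups), function(gi) {
    g <- groups[gi]; n <- sizes[gi]
    cols <- lapply(metrics, function(mt) {
      row <- spec[spec$group == g & spec$metric == mt, ]
      if (nrow(row) == 0) return(rep(NA_real_, n))
      draw(n, row$mean[1], row$sd[1])
    })
    names(cols) <- metrics
    tibble(
      subject_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g, !!!cols
    )
  })
  out <- bind_rows(out)
  out$group <- factor(out$group, levels = groups)
  out
}
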