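#' Plot a flow curve
#'
#' Per-phase CSF flow over one cardiac cycle, cranial-positive, with the
#' zero-flow line marked.
#'
#' @param object A [flow_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_curve <- function(object, ...) {
  df <- tibble(time = object$times, flow = object$q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$flow)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time in cycle (s)", y = "Flow (mL/s)",
                  title = "CSF flow over one cardiac cycle",
                  subtitle = "Cranial flow positive") +
    ggplot2::theme_minimal()
}

#' @export
plot.flow_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot a segmentation mask over its NCC map
#'
#' @param object A `csf_mask` from [pubs_mask()].
#' @param ... Unused.
#' @return A ggplot: NCC raster with the segmented voxels outlined.
#' @export
autoplot.csf_mask <- function(object, ...) {
  idx <- which(!is.na(object$ncc_map), arr.ind = TRUE)
  df <- tibble(row = idx[, 1], col = idx[, 2],
               ncc = object$ncc_map[idx],
               selected = object$mask[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$ncc)) +
    ggplot2::geom_point(data = df[df$selected, ], shape = 0, size = 1,
                        colour = "black") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("PUBS mask (NCC >= %.2f)",
                                  object$threshold),
                  x = NULL, y = NULL, fill = "NCC") +
    ggplot2::theme_minimal()
}

#' @export
plot.csf_mask <- function(x, ...) print(autoplot(x, ...))

#' Plot a reference waveform
#'
#' @param object A `reference_waveform` from [ica_reference()].
#' @param ... Unused.
#' @return A ggplot of the normalized template over the cycle.
#' @export
autoplot.reference_waveform <- function(object, ...) {
  df <- tibble(phase = seq_along(object$trace), value = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cardiac phase", y = "Normalized velocity",
                  title = "ICA-derived CSF reference waveform") +
    ggplot2::theme_minimal()
}

#' @export
plot.reference_waveform <- function(x, ...) print(autoplot(x, ...))

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc()].
#' @param ... Unused.
#' @return A ggplot of the empirical ROC with the Youden-optimal point
#'   marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  cv <- object$curve
  df <- tibble(fpr = 1 - cv$specificity, tpr = cv$sensitivity)
  df <- df[order(df$fpr, df$tpr), ]
  df <- bind_rows(tibble(fpr = 0, tpr = 0), df, tibble(fpr = 1, tpr = 1))
  best <- tibble(fpr = 1 - object$specificity / 100,
                 tpr = object$sensitivity / 100)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = best, colour = "firebrick", size = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc),
                  subtitle = sprintf("Cutoff %.4f: sens %.1f%%, spec %.1f%%",
                                     object$cutoff, object$sensitivity,
                                     object$specificity)) +
    ggplot2::theme_minimal()
}

#' @export
plot.roc_result <- function(x, ...) print(autoplot(x, ...))
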