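# Internal constructor shared by flow_curve() and the scene generator.
new_flow_curve <- function(q, pixel_area, n_phases, rr_duration) {
  structure(
    list(q = q, pixel_area = pixel_area, n_phases = n_phases,
         rr_duration = rr_duration,
         times = (seq_len(n_phases) - 0.5) / n_phases * rr_duration),
    class = "flow_curve"
  )
}

#' Flow curve over the cardiac cycle
#'
#' Integrates velocity over the segmented CSF area at each cardiac phase:
#' `q[t] = sum(v[t, voxel]) * pixel_area`, with `pixel_area =
#' (pixel_spacing / 10)^2` cm², so `q` is in mL/s (cranial-positive).
#'
#' @param vel A `velocity_series` (background-corrected for quantitative
#'   use).
#' @param mask A `csf_mask` or logical `H x W` matrix; must be nonempty.
#' @param pixel_spacing Pixel spacing in mm; defaults to the series metadata.
#' @return A `flow_curve` with `q` (length T, mL/s), `pixel_area`,
#'   `n_phases`, `rr_duration` and sample `times`.
#' @export
flow_curve <- function(vel, mask, pixel_spacing = NULL) {
  stopifnot(inherits(vel, "velocity_series"))
  m <- if (inherits(mask, "csf_mask")) mask$mask else mask
  d <- dim(vel$velocity)
  if (!identical(dim(m), d[2:3])) {
    abort("Mask dimensions do not match the velocity series.",
          class = "csfflow_format_error")
  }
  if (!any(m)) {
    abort("Empty CSF mask: no voxels to integrate.",
          class = "csfflow_segmentation_error")
  }
  ps <- pixel_spacing %||% vel$pixel_spacing
  area <- (ps / 10)^2
  V <- matrix(vel$velocity, nrow = d[1])
  q <- rowSums(V[, as.vector(m), drop = FALSE]) * area
  new_flow_curve(q, area, d[1], vel$rr_duration)
}

#' Construct a set of directional flow metrics
#'
#' Builds the tabulated flow-metric set from its directional components and
#' enforces the defining identities: summation metrics are the sum of their
#' directional parts, the absolute stroke volume is the sum of the
#' directional per-cycle totals, and the net output is their signed
#' difference (unless supplied). All directional values must be
#' non-negative.
#'
#' @param upward_mean_flow,downward_mean_flow Directional mean flow, mL/s.
#' @param upward_peak_flow,downward_peak_flow Directional peak flow, mL/s.
#' @param upward_total_flow,downward_total_flow Directional per-cycle totals,
#'   mL/cycle.
#' @param net_output Signed per-cycle output, mL/cycle; defaults to
#'   `upward_total_flow - downward_total_flow`.
#' @param n_phases Optional cardiac phase count carried as an attribute (used
#'   to validate acquisition combination).
#' @return A `flow_metrics` object (a named list of the ten metric fields).
#' @examples
#' fm <- flow_metrics(upward_total_flow = 14.32, downward_total_flow = 13.22)
#' fm$absolute_stroke_volume
#' @export
flow_metrics <- function(upward_mean_flow = 0, downward_mean_flow = 0,
                         upward_peak_flow = 0, downward_peak_flow = 0,
                         upward_total_flow = 0, downward_total_flow = 0,
                         net_output = NULL, n_phases = NA_integer_) {
  directional <- c(upward_mean_flow, downward_mean_flow, upward_peak_flow,
                   downward_peak_flow, upward_total_flow, downward_total_flow)
  if (any(!is.finite(directional)) || any(directional < 0)) {
    abort("Directional flow metrics must be finite and non-negative.",
          class = "csfflow_config_error")
  }
  structure(
    list(
      upward_mean_flow = upward_mean_flow,
      downward_mean_flow = downward_mean_flow,
      summation_mean_flow = upward_mean_flow + downward_mean_flow,
      upward_peak_flow = upward_peak_flow,
      downward_peak_flow = downward_peak_flow,
      summation_peak_flow = upward_peak_flow + downward_peak_flow,
      upward_total_flow = upward_total_flow,
      downward_total_flow = downward_total_flow,
      absolute_stroke_volume = upward_total_flow + downward_total_flow,
      net_output = net_output %||% (upward_total_flow - downward_total_flow)
    ),
    n_phases = n_phases,
    class = "flow_metrics"
  )
}

#' @export
print.flow_metrics <- function(x, digits = 3, ...) {
  cat("<flow_metrics>\n")
  for (f in metric_fields()) {
    cat(sprintf("  %-24s %s\n", f, format(x[[f]], digits = digits)))
  }
  invisible(x)
}

#' Compute the flow-metric set from a flow curve
#'
#' Direction is decided by the sign of the per-phase net flow `q[t]`:
#' cranial (upward) phases have `q[t] > 0`, caudal (downward) `q[t] < 0`,
#' and exact zeros belong to neither direction. Directional means and peaks
#' are taken over each direction's phases; directional totals are the sums of
#' the direction's samples (labelled mL/cycle), which makes the ratio of a
#' direction's total to its mean equal to its phase count. With
#' `time_integrated = TRUE`, totals and net output are instead integrated in
#' time (`q * rr_duration / n_phases`, true mL per cycle).
#'
#' @param fc A [flow_curve()].
#' @param time_integrated Scale per-cycle totals by the phase duration.
#' @return A [flow_metrics()] object. An empty direction yields 0 for that
#'   direction's metrics.
#' @examples
#' fc <- csfflow:::new_flow_curve(c(2, 2, -1, -1, -1, -1), 1e-2, 6, 1)
#' compute_metrics(fc)$absolute_stroke_volume
#' @export
compute_metrics <- function(fc, time_integrated = FALSE) {
  stopifnot(inherits(fc, "flow_curve"))
  q <- fc$q
  up <- q[q > 0]
  dn <- -q[q < 0]
  scale <- if (time_integrated) fc$rr_duration / fc$n_phases else 1
  flow_metrics(
    upward_mean_flow = if (length(up)) mean(up) else 0,
    downward_mean_flow = if (length(dn)) mean(dn) else 0,
    upward_peak_flow = if (length(up)) max(up) else 0,
    downward_peak_flow = if (length(dn)) max(dn) else 0,
    upward_total_flow = sum(up) * scale,
    downward_total_flow = sum(dn) * scale,
    net_output = sum(q) * scale,
    n_phases = fc$n_phases
  )
}

#' Average flow metrics over repeated acquisitions
#'
#' Consecutive acquisitions of the same session are combined by the
#' element-wise arithmetic mean of their metric sets, which minimizes
#' physiological and noise variability while staying robust to small
#' inter-acquisition misregistration (metrics, not raw images, are averaged).
#'
#' @param metrics A list of [flow_metrics()] (typically three), or several
#'   `flow_metrics` passed as `...`.
#' @param ... Additional `flow_metrics` objects.
#' @return The combined `flow_metrics`.
#' @export
combine_acquisitions <- function(metrics, ...) {
  if (inherits(metrics, "flow_metrics")) metrics <- list(metrics, ...)
  if (!length(metrics) || !all(vapply(metrics, inherits, logical(1),
                                      "flow_metrics"))) {
    abort("`metrics` must be flow_metrics objects.",
          class = "csfflow_config_error")
  }
  np <- vapply(metrics, function(m) as.integer(attr(m, "n_phases")),
               integer(1))
  known <- np[!is.na(np)]
  if (length(unique(known)) > 1) {
    abort("Acquisitions have mismatched cardiac phase counts.",
          class = "csfflow_config_error")
  }
  avg <- function(f) mean(vapply(metrics, `[[`, numeric(1), f))
  flow_metrics(
    upward_mean_flow = avg("upward_mean_flow"),
    downward_mean_flow = avg("downward_mean_flow"),
    upward_peak_flow = avg("upward_peak_flow"),
    downward_peak_flow = avg("downward_peak_flow"),
    upward_total_flow = avg("upward_total_flow"),
    downward_total_flow = avg("downward_total_flow"),
    net_output = avg("net_output"),
    n_phases = if (length(known)) known[1] else NA_integer_
  )
}

#' @export
as_tibble.flow_metrics <- function(x, ...) {
  as_tibble(setNames(lapply(metric_fields(), function(f) x[[f]]),
                     metric_fields()))
}

#' Tidy a flow-metric set into a long tibble
#'
#' @param x A [flow_metrics()] object.
#' @param ... Unused.
#' @return A tibble with `metric`, `value`, `unit`.
#' @export
tidy.flow_metrics <- function(x, ...) {
  tibble(
    metric = metric_fields(),
    value = vapply(metric_fields(), function(f) x[[f]], numeric(1)),
    unit = c(rep("mL/s", 6), rep("mL/cycle", 4))
  )
}
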