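#' Axis-aligned bounding box
#'
#' Pixel coordinates are 0-based and half-open: the box covers columns
#' `[x, x + w)` and rows `[y, y + h)`.
#'
#' @param x,y Origin (column, row), 0-based.
#' @param w,h Extent in pixels (> 0).
#' @param score Detection confidence in `[0, 1]`.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(x, y, w, h, score = 1) {
  if (w <= 0 || h <= 0) {
    abort("Box extents `w` and `h` must be positive.",
          class = "csfflow_config_error")
  }
  if (x < 0 || y < 0) {
    abort("Box origin must be non-negative.", class = "csfflow_config_error")
  }
  check_number(score, "score", min = 0, max = 1)
  structure(list(x = x, y = y, w = w, h = h, score = score),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> x=%g y=%g w=%g h=%g score=%.3f\n",
              x$x, x$y, x$w, x$h, x$score))
  invisible(x)
}

# 1-based row/column index ranges covered by a box.
box_rows <- function(box) (box$y + 1):(box$y + box$h)
box_cols <- function(box) (box$x + 1):(box$x + box$w)

check_box_inside <- function(box, H, W) {
  if (box$x + box$w > W || box$y + box$h > H) {
    abort("Bounding box extends beyond the image.",
          class = "csfflow_config_error")
  }
  invisible(box)
}

#' Intersection over union of two boxes
#'
#' @param a,b [bounding_box()] objects.
#' @return IoU in `[0, 1]`: 1 for identical boxes, 0 for disjoint ones.
#' @examples
#' iou(bounding_box(0, 0, 2, 2), bounding_box(1, 0, 2, 2)) # 2/6
#' @export
iou <- function(a, b) {
  iw <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  ih <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Detect the spinal canal on a cine acquisition
#'
#' The built-in detector is classical: it decodes velocities, builds a
#' temporal-pulsatility saliency map (per-voxel temporal SD), smooths it with
#' a Gaussian, thresholds by Otsu's method, takes the tightest box around the
#' largest connected component, and pads it by a margin. It stands behind the
#' same contract as any trained detector; externally produced boxes (e.g.
#' from a fine-tuned object-detection network) are accepted via
#' `mode = "external"` and passed through unchanged.
#'
#' @param series A [cine_series()].
#' @param margin Padding in pixels added around the tight component box.
#' @param smooth_sigma Gaussian smoothing sigma (pixels) for the saliency map.
#' @param min_saliency Minimum saliency dynamic range (cm/s); an essentially
#'   static image raises a no-detection error.
#' @param mode `"builtin"` or `"external"`.
#' @param external_box The [bounding_box()] to pass through when
#'   `mode = "external"`.
#' @return A [bounding_box()]; `score` is the mean normalized saliency of the
#'   detected component.
#' @export
detect_canal <- function(series, margin = 2, smooth_sigma = 1.5,
                         min_saliency = 1e-6,
                         mode = c("builtin", "external"),
                         external_box = NULL) {
  mode <- match.arg(mode)
  if (mode == "external") {
    if (!inherits(external_box, "bounding_box")) {
      abort("`external_box` must be a bounding_box in external mode.",
            class = "csfflow_config_error")
    }
    return(external_box)
  }
  stopifnot(inherits(series, "cine_series"))
  vel <- phase_to_velocity(series)
  H <- dim(vel$velocity)[2]; W <- dim(vel$velocity)[3]
  sal <- temporal_sd_map(vel$velocity)
  rng <- range(sal)
  if (diff(rng) < min_saliency) {
    abort("No pulsatile region found: saliency map is flat (static image).",
          class = "csfflow_detection_error")
  }
  if (smooth_sigma > 0) {
    sal <- EBImage::imageData(EBImage::gblur(sal, sigma = smooth_sigma))
    rng <- range(sal)
  }
  sal <- (sal - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(sal, range = c(0, 1))
  bw <- sal > thr
  if (!any(bw)) {
    abort("No pulsatile region found above the Otsu threshold.",
          class = "csfflow_detection_error")
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), H, W))
  lab <- EBImage::imageData(lab)
  comp <- lab == which.max(tabulate(lab[lab > 0]))
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  y0 <- max(0, rows[1] - 1 - margin)
  x0 <- max(0, cols[1] - 1 - margin)
  y1 <- min(H, rows[2] + margin)
  x1 <- min(W, cols[2] + margin)
  bounding_box(x = x0, y = y0, w = x1 - x0, h = y1 - y0,
               score = min(1, mean(sal[comp])))
}

#' Average precision of ranked detections
#'
#' Standard ranked-detection evaluation at a fixed IoU threshold: detections
#' are sorted by confidence, each may match at most one not-yet-matched truth
#' box in its image at `IoU >= iou_min`, and AP is the area under the
#' all-points (continuous) precision-recall curve.
#'
#' @param detections Data frame with columns `image_id`, `x`, `y`, `w`, `h`,
#'   `score`.
#' @param truths Data frame with columns `image_id`, `x`, `y`, `w`, `h`
#'   (at least one row).
#' @param iou_min Minimum IoU for a detection to count as a hit.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(detections, truths, iou_min = 0.5) {
  if (is.null(truths) || nrow(truths) == 0) {
    abort("At least one ground-truth box is required.",
          class = "csfflow_config_error")
  }
  n_truth <- nrow(truths)
  if (is.null(detections) || nrow(detections) == 0) return(0)

  ord <- order(-detections$score)
  matched <- logical(n_truth)
  tp <- numeric(length(ord))
  for (k in seq_along(ord)) {
    d <- detections[ord[k], ]
    db <- bounding_box(d$x, d$y, d$w, d$h)
    cand <- which(truths$image_id == d$image_id & !matched)
    if (length(cand) > 0) {
      ious <- vapply(cand, function(i) {
        iou(db, bounding_box(truths$x[i], truths$y[i],
                             truths$w[i], truths$h[i]))
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_min) {
        matched[cand[best]] <- TRUE
        tp[k] <- 1
      }
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_truth
  # All-points interpolation: precision envelope from the right.
  envelope <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * envelope)
}
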