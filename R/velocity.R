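#' Decode phase to velocity
#'
#' Applies the standard PC-MRI scaling `v = venc * phi / pi` voxel-wise, so a
#' phase of `pi` maps to the velocity-encoding limit. The transform is linear
#' and odd; decoded magnitudes cannot exceed `venc` before background
#' correction.
#'
#' @param series A [cine_series()].
#' @return A `velocity_series`: signed velocities in cm/s (`T x H x W`), with
#'   the acquisition metadata and a `background_corrected` provenance flag.
#' @examples
#' sc <- render_scene(scene_config(seed = 1, noise_sd = 0))
#' vel <- phase_to_velocity(sc$series[[1]])
#' range(vel$velocity)
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_series"))
  structure(
    list(
      velocity = series$venc * series$phase / pi,
      venc = series$venc, n_phases = series$n_phases,
      pixel_spacing = series$pixel_spacing,
      rr_duration = series$rr_duration,
      acquisition_id = series$acquisition_id,
      background_corrected = FALSE
    ),
    class = "velocity_series"
  )
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf(
    "<velocity_series %s> %d phases, %d x %d px, venc %.1f cm/s%s\n",
    x$acquisition_id, d[1], d[2], d[3], x$venc,
    if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Correct background phase offsets
#'
#' Hardware imperfections (eddy currents, concomitant gradients) shift the
#' phase of static tissue away from zero as a spatially smooth field. This
#' fits a low-order 2D polynomial (default: a plane) to the temporal-mean
#' velocity of static voxels by least squares and subtracts the fitted field
#' from every frame. Being constant in time, the correction leaves each
#' voxel's pulsatile component — its temporal standard deviation — unchanged.
#'
#' Static voxels are either supplied as a mask or auto-selected as the
#' voxels with the lowest temporal standard deviation (default: lowest 30%),
#' optionally restricted to outside the detected canal box.
#'
#' @param vel A `velocity_series` from [phase_to_velocity()].
#' @param static_mask Optional `H x W` logical matrix of known-static voxels.
#' @param degree Polynomial degree of the offset model (default 1).
#' @param exclude_box Optional [bounding_box()] excluded from auto-selection
#'   (typically the detected canal).
#' @param static_quantile Quantile of temporal SD below which voxels are
#'   treated as static when auto-selecting.
#' @return The corrected `velocity_series` (`background_corrected = TRUE`),
#'   with attributes `static_mask`, `field` (the subtracted cm/s field) and
#'   `coefficients`.
#' @export
correct_background <- function(vel, static_mask = NULL, degree = 1,
                               exclude_box = NULL, static_quantile = 0.3) {
  stopifnot(inherits(vel, "velocity_series"))
  d <- dim(vel$velocity)
  T <- d[1]; H <- d[2]; W <- d[3]
  V <- matrix(vel$velocity, nrow = T)
  mean_map <- colMeans(V)

  if (is.null(static_mask)) {
    sd_map <- as.vector(temporal_sd_map(vel$velocity))
    candidate <- rep(TRUE, H * W)
    if (!is.null(exclude_box)) {
      bm <- matrix(FALSE, H, W)
      bm[box_rows(exclude_box), box_cols(exclude_box)] <- TRUE
      candidate <- !as.vector(bm)
    }
    thr <- quantile(sd_map[candidate], static_quantile, names = FALSE)
    static <- candidate & sd_map <= thr
  } else {
    if (!identical(dim(static_mask), c(H, W))) {
      abort("`static_mask` must match the image dimensions.",
            class = "csfflow_format_error")
    }
    static <- as.vector(static_mask)
  }

  X <- poly_basis(H, W, degree)
  if (sum(static) < ncol(X)) {
    abort(sprintf(
      "Only %d static voxels for %d polynomial coefficients: cannot fit the background model.",
      sum(static), ncol(X)),
      class = "csfflow_correction_error"
    )
  }
  fit <- lm.fit(X[static, , drop = FALSE], mean_map[static])
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  field <- as.vector(X %*% beta)

  out <- vel
  out$velocity <- array(V - rep(field, each = T), dim = d)
  out$background_corrected <- TRUE
  attr(out, "static_mask") <- matrix(static, H, W)
  attr(out, "field") <- matrix(field, H, W)
  attr(out, "coefficients") <- beta
  out
}
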