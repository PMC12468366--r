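#' Configuration for a synthetic cine PC-MRI scene
#'
#' Describes an axial C2-like slice: an annular CSF space with a pulsatile
#' biphasic waveform, optional venous voxels with a distinct lagged waveform,
#' static tissue, a spatially smooth background phase offset, and acquisition
#' noise, replicated as several consecutive gated acquisitions. Defaults
#' emulate the acquisition protocol this pipeline targets: 32 cardiac phases,
#' low velocity encoding (venc 10 cm/s), three consecutive acquisitions.
#'
#' @param image_size Height and width in pixels (length-2 integer).
#' @param n_phases Cardiac phases per cycle (>= 8).
#' @param pixel_spacing Isotropic pixel spacing in mm.
#' @param venc Velocity-encoding limit in cm/s; velocities beyond it alias.
#' @param rr_duration R-R interval in seconds.
#' @param center Annulus center `(row, col)` in pixels; defaults to the image
#'   center.
#' @param inner_radius,outer_radius Annulus radii in pixels
#'   (`inner_radius < outer_radius`).
#' @param csf_peak_up,csf_peak_down Peak cranial/caudal CSF velocity, cm/s.
#' @param systolic_fraction Caudal-lobe fraction of the cycle.
#' @param venous_fraction Proportion of non-CSF voxels inside the canal
#'   bounding box given a venous waveform.
#' @param venous_peak Peak venous velocity, cm/s.
#' @param venous_phase_lag Venous pulse lag as a fraction of the cycle.
#' @param noise_sd Velocity-noise standard deviation in cm/s (per voxel and
#'   phase, independent across acquisitions).
#' @param background_coef Coefficients of the background phase-offset field in
#'   radians over normalized image coordinates; length 1, 3 or 6 for degree
#'   0, 1 or 2.
#' @param n_acquisitions Number of consecutive acquisitions to replicate.
#' @param allow_wrap If `FALSE` (default), configurations whose peak velocity
#'   reaches `venc` are rejected with a velocity-aliasing error; if `TRUE`
#'   the phase is wrapped instead.
#' @param seed Integer seed; fixed seeds give bit-identical scenes.
#' @return A validated `scene_config` object.
#' @export
scene_config <- function(image_size = c(64, 64), n_phases = 32,
                         pixel_spacing = 0.6, venc = 10, rr_duration = 0.9,
                         center = NULL, inner_radius = 8, outer_radius = 14,
                         csf_peak_up = 1.5, csf_peak_down = 2.4,
                         systolic_fraction = 0.45,
                         venous_fraction = 0.1, venous_peak = 1,
                         venous_phase_lag = 0.25, noise_sd = 0.2,
                         background_coef = c(0.05, 0.04, -0.03),
                         n_acquisitions = 3, allow_wrap = FALSE, seed = NULL) {
  if (length(image_size) != 2 || any(image_size < 8)) {
    abort("`image_size` must be two pixel counts >= 8.",
          class = "csfflow_config_error")
  }
  if (!is.numeric(n_phases) || n_phases < 8 || n_phases != round(n_phases)) {
    abort("`n_phases` must be an integer >= 8.", class = "csfflow_config_error")
  }
  check_number(pixel_spacing, "pixel_spacing", min = 0, strict_min = TRUE)
  check_number(venc, "venc", min = 0, strict_min = TRUE)
  check_number(rr_duration, "rr_duration", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(venous_fraction, "venous_fraction", min = 0, max = 1,
               strict_max = TRUE)
  if (inner_radius >= outer_radius) {
    abort("`inner_radius` must be smaller than `outer_radius`.",
          class = "csfflow_config_error")
  }
  center <- center %||% ((image_size + 1) / 2)
  if (any(center - outer_radius < 1) ||
      center[1] + outer_radius > image_size[1] ||
      center[2] + outer_radius > image_size[2]) {
    abort("CSF annulus does not fit inside the image.",
          class = "csfflow_config_error")
  }
  poly_degree_from_coef(background_coef) # validates length
  if (n_acquisitions < 1) {
    abort("`n_acquisitions` must be >= 1.", class = "csfflow_config_error")
  }

  structure(
    list(
      image_size = as.integer(image_size), n_phases = as.integer(n_phases),
      pixel_spacing = pixel_spacing, venc = venc, rr_duration = rr_duration,
      center = center, inner_radius = inner_radius,
      outer_radius = outer_radius, csf_peak_up = csf_peak_up,
      csf_peak_down = csf_peak_down, systolic_fraction = systolic_fraction,
      venous_fraction = venous_fraction, venous_peak = venous_peak,
      venous_phase_lag = venous_phase_lag, noise_sd = noise_sd,
      background_coef = background_coef,
      n_acquisitions = as.integer(n_acquisitions),
      allow_wrap = allow_wrap, seed = seed
    ),
    class = "scene_config"
  )
}

# Background phase-offset field (radians) implied by a scene config, H x W.
background_field <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  degree <- poly_degree_from_coef(config$background_coef)
  X <- poly_basis(H, W, degree)
  matrix(as.vector(X %*% config$background_coef), nrow = H, ncol = W)
}

#' Render a synthetic cine PC-MRI scene with ground truth
#'
#' Realizes the three signal classes of the spinal canal — flowing CSF,
#' venous blood, and static tissue — as magnitude/phase stacks. Velocity is
#' encoded into phase as `phi = pi * v / venc` plus the background offset
#' field, wrapped into `[-pi, pi)`. Each acquisition shares geometry and
#' waveforms but receives independent noise. Ground-truth metrics are
#' computed analytically from the noise-free CSF waveform.
#'
#' @param config A [scene_config()].
#' @return A list with `series` (list of [cine_series()] objects, one per
#'   acquisition) and `truth`, a `scene_truth` holding `csf_mask`,
#'   `venous_mask`, `canal_bbox`, `true_waveform` (cm/s), `true_flow_curve`
#'   (mL/s), `true_metrics` and `background` (radians).
#' @examples
#' sc <- render_scene(scene_config(seed = 1, noise_sd = 0))
#' dim(sc$series[[1]]$phase)
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  H <- config$image_size[1]; W <- config$image_size[2]
  T <- config$n_phases
  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
  r2 <- (rr - config$center[1])^2 + (cc - config$center[2])^2
  csf_mask <- r2 > config$inner_radius^2 & r2 <= config$outer_radius^2

  rows <- range(which(rowSums(csf_mask) > 0))
  cols <- range(which(colSums(csf_mask) > 0))
  canal_bbox <- bounding_box(
    x = cols[1] - 1, y = rows[1] - 1,
    w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1, score = 1
  )

  in_box <- rr >= rows[1] & rr <= rows[2] & cc >= cols[1] & cc <= cols[2]
  venous_mask <- matrix(FALSE, H, W)
  cand <- which(in_box & !csf_mask)
  n_ven <- round(config$venous_fraction * length(cand))
  if (n_ven > 0) venous_mask[sample(cand, n_ven)] <- TRUE

  v_extreme <- max(config$csf_peak_up, config$csf_peak_down,
                   if (n_ven > 0) config$venous_peak else 0)
  if (v_extreme >= config$venc && !config$allow_wrap) {
    abort(
      sprintf(paste0(
        "Peak velocity %.2f cm/s reaches venc = %.2f cm/s: phase would ",
        "alias. Lower the peaks, raise venc, or set `allow_wrap = TRUE`."),
        v_extreme, config$venc),
      class = "csfflow_aliasing_error"
    )
  }

  csf_wave <- make_csf_waveform(T, config$csf_peak_up, config$csf_peak_down,
                                config$systolic_fraction)
  ven_wave <- make_venous_waveform(T, config$venous_peak,
                                   config$venous_phase_lag)
  bg <- background_field(config)

  # Noise-free velocity, T x (H*W) with columns in H x W column-major order.
  V0 <- matrix(0, nrow = T, ncol = H * W)
  V0[, which(csf_mask)] <- csf_wave
  if (n_ven > 0) V0[, which(venous_mask)] <- ven_wave

  base_mag <- matrix(0.25, H, W)
  base_mag[in_box] <- 0.55
  base_mag[venous_mask] <- 0.75
  base_mag[csf_mask] <- 0.95

  series <- vector("list", config$n_acquisitions)
  for (i in seq_len(config$n_acquisitions)) {
    Vn <- V0
    if (config$noise_sd > 0) {
      Vn <- Vn + matrix(rnorm(T * H * W, sd = config$noise_sd), nrow = T)
    }
    phi <- pi * Vn / config$venc + rep(as.vector(bg), each = T)
    phi <- wrap_phase(phi)
    mag <- rep(as.vector(base_mag), each = T)
    if (config$noise_sd > 0) mag <- mag + rnorm(T * H * W, sd = 0.02)
    series[[i]] <- cine_series(
      magnitude = array(pmax(mag, 0.01), dim = c(T, H, W)),
      phase = array(phi, dim = c(T, H, W)),
      venc = config$venc, pixel_spacing = config$pixel_spacing,
      rr_duration = config$rr_duration,
      acquisition_id = sprintf("acq%02d", i)
    )
  }

  pixel_area <- (config$pixel_spacing / 10)^2 # cm^2
  true_q <- csf_wave * sum(csf_mask) * pixel_area
  true_fc <- new_flow_curve(true_q, pixel_area, T, config$rr_duration)

  truth <- structure(
    list(
      csf_mask = csf_mask, venous_mask = venous_mask,
      canal_bbox = canal_bbox, true_waveform = csf_wave,
      true_flow_curve = true_q, true_metrics = compute_metrics(true_fc),
      background = bg, n_csf_voxels = sum(csf_mask), config = config
    ),
    class = "scene_truth"
  )
  list(series = series, truth = truth)
}
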