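#' A gated cine phase-contrast acquisition
#'
#' Container for one ECG-gated cine PC-MRI acquisition: a magnitude stack and
#' a velocity-encoded phase stack (radians in `[-pi, pi)`), both `T x H x W`,
#' together with the metadata needed to decode velocities and scale flow.
#'
#' @param magnitude,phase Numeric arrays of identical dimension
#'   `c(n_phases, height, width)`; phase in radians within `[-pi, pi)`.
#' @param venc Velocity-encoding limit in cm/s (> 0).
#' @param pixel_spacing Isotropic pixel spacing in mm (> 0).
#' @param rr_duration R-R interval in seconds (> 0).
#' @param acquisition_id Label distinguishing repeated acquisitions.
#' @param trigger_times Optional per-frame trigger times (ms); frames are
#'   expected in trigger order.
#' @return A `cine_series` object.
#' @export
cine_series <- function(magnitude, phase, venc, pixel_spacing, rr_duration,
                        acquisition_id = "acq01", trigger_times = NULL) {
  if (!is.array(magnitude) || !is.array(phase) ||
      length(dim(magnitude)) != 3 || !identical(dim(magnitude), dim(phase))) {
    abort("`magnitude` and `phase` must be T x H x W arrays of equal shape.",
          class = "csfflow_format_error")
  }
  check_number(venc, "venc", min = 0, strict_min = TRUE)
  check_number(pixel_spacing, "pixel_spacing", min = 0, strict_min = TRUE)
  check_number(rr_duration, "rr_duration", min = 0, strict_min = TRUE)
  eps <- 1e-9
  if (any(!is.finite(phase)) ||
      min(phase) < -pi - eps || max(phase) >= pi + eps) {
    abort("Phase values must be finite radians in [-pi, pi).",
          class = "csfflow_format_error")
  }
  n_phases <- dim(phase)[1]
  if (!is.null(trigger_times) && length(trigger_times) != n_phases) {
    abort("`trigger_times` must have one entry per cardiac phase.",
          class = "csfflow_format_error")
  }
  structure(
    list(
      magnitude = magnitude, phase = phase, venc = venc,
      n_phases = n_phases, pixel_spacing = pixel_spacing,
      rr_duration = rr_duration, acquisition_id = acquisition_id,
      trigger_times = trigger_times
    ),
    class = "cine_series"
  )
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "<cine_series %s> %d phases, %d x %d px, venc %.1f cm/s, RR %.2f s\n",
    x$acquisition_id, d[1], d[2], d[3], x$venc, x$rr_duration))
  invisible(x)
}

series_meta <- function(series, dialect) {
  list(
    dialect = dialect, venc = series$venc, n_phases = series$n_phases,
    pixel_spacing = series$pixel_spacing, rr_duration = series$rr_duration,
    acquisition_id = series$acquisition_id,
    trigger_times = series$trigger_times
  )
}

#' Write a cine series to disk
#'
#' Serializes a [cine_series()] into a directory: a `meta.json` sidecar with
#' the acquisition metadata plus either NIfTI stacks (`dialect = "nifti"`,
#' frames along the third axis) or a single long-format `voxels.csv`
#' (`dialect = "csv"`, a plain-text dialect suited to small fixtures).
#'
#' @param series A [cine_series()].
#' @param path Output directory (created if missing).
#' @param dialect `"nifti"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, dialect = c("nifti", "csv")) {
  stopifnot(inherits(series, "cine_series"))
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(series_meta(series, dialect),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (dialect == "nifti") {
    RNifti::writeNifti(aperm(series$magnitude, c(2, 3, 1)),
                       file.path(path, "magnitude.nii.gz"))
    RNifti::writeNifti(aperm(series$phase, c(2, 3, 1)),
                       file.path(path, "phase.nii.gz"))
  } else {
    d <- dim(series$phase)
    df <- data.frame(
      frame = rep(seq_len(d[1]), times = d[2] * d[3]),
      row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      col = rep(seq_len(d[3]), each = d[1] * d[2]),
      magnitude = as.vector(series$magnitude),
      phase = as.vector(series$phase)
    )
    write.csv(df, file.path(path, "voxels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a cine series from disk
#'
#' Reads a directory written by [write_series()] (or assembled to the same
#' layout). Metadata missing from the sidecar — in particular `venc` — is a
#' hard error, since phase cannot be decoded without it. If per-frame
#' `trigger_times` are present and out of order, frames are re-sorted by
#' trigger time with the frame count preserved.
#'
#' @param path Directory containing `meta.json` and image data.
#' @param dialect `"nifti"` or `"csv"`; defaults to the dialect recorded in
#'   the sidecar.
#' @return A validated [cine_series()].
#' @export
read_series <- function(path, dialect = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("No meta.json sidecar found under '%s'.", path),
          class = "csfflow_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("venc", "pixel_spacing", "rr_duration")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("Sidecar metadata is missing `%s`; supply it to decode.",
                    field),
            class = "csfflow_metadata_error")
    }
  }
  dialect <- dialect %||% meta$dialect %||% "nifti"
  if (!dialect %in% c("nifti", "csv")) {
    abort(sprintf("Unsupported dialect '%s'.", dialect),
          class = "csfflow_format_error")
  }

  if (dialect == "nifti") {
    mag <- as.array(RNifti::readNifti(file.path(path, "magnitude.nii.gz")))
    phs <- as.array(RNifti::readNifti(file.path(path, "phase.nii.gz")))
    if (length(dim(mag)) != 3 || !identical(dim(mag), dim(phs))) {
      abort("Magnitude and phase stacks have inconsistent shapes.",
            class = "csfflow_format_error")
    }
    mag <- aperm(mag, c(3, 1, 2))
    phs <- aperm(phs, c(3, 1, 2))
  } else {
    df <- read.csv(file.path(path, "voxels.csv"))
    need <- c("frame", "row", "col", "magnitude", "phase")
    if (!all(need %in% names(df))) {
      abort("voxels.csv must have frame,row,col,magnitude,phase columns.",
            class = "csfflow_format_error")
    }
    d <- c(max(df$frame), max(df$row), max(df$col))
    if (nrow(df) != prod(d) || anyNA(df)) {
      abort("voxels.csv does not cover the full frame x row x col grid.",
            class = "csfflow_format_error")
    }
    idx <- cbind(df$frame, df$row, df$col)
    mag <- array(NA_real_, d); mag[idx] <- df$magnitude
    phs <- array(NA_real_, d); phs[idx] <- df$phase
  }

  if (!is.null(meta$n_phases) && dim(phs)[1] != meta$n_phases) {
    abort(sprintf("Sidecar declares %d cardiac phases but stacks hold %d.",
                  meta$n_phases, dim(phs)[1]),
          class = "csfflow_format_error")
  }

  tt <- meta$trigger_times
  if (!is.null(tt) && length(tt) > 0) {
    if (length(tt) != dim(phs)[1]) {
      abort("`trigger_times` length does not match the number of frames.",
            class = "csfflow_format_error")
    }
    ord <- order(tt)
    if (!identical(ord, seq_along(tt))) {
      mag <- mag[ord, , , drop = FALSE]
      phs <- phs[ord, , , drop = FALSE]
      tt <- tt[ord]
    }
  } else {
    tt <- NULL
  }

  cine_series(
    magnitude = mag, phase = phs, venc = meta$venc,
    pixel_spacing = meta$pixel_spacing, rr_duration = meta$rr_duration,
    acquisition_id = meta$acquisition_id %||% "acq01",
    trigger_times = tt
  )
}
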