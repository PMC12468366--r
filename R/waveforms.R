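#' Canonical biphasic CSF velocity waveform
#'
#' Builds one cardiac cycle of a smooth, periodic through-plane CSF velocity
#' trace at the cervical subarachnoid space: a caudal (negative, systolic)
#' lobe followed by a cranial (positive, diastolic) lobe. Cranial flow is
#' positive by package convention. Samples are placed at cardiac-phase
#' centers, `t = (k + 1/2)/T`, so no sample falls exactly on a zero crossing;
#' each lobe is rescaled so the sampled extrema equal the requested peaks
#' exactly.
#'
#' @param n_phases Number of cardiac phases per cycle (>= 8; scanners here
#'   acquire 32).
#' @param peak_up Peak cranial velocity in cm/s (> 0).
#' @param peak_down Peak caudal velocity magnitude in cm/s (> 0).
#' @param systolic_fraction Fraction of the cycle occupied by the caudal
#'   (systolic) lobe, strictly between 0 and 1.
#'
#' @return Numeric vector of length `n_phases`, in cm/s; `max` equals
#'   `peak_up`, `min` equals `-peak_down`.
#' @examples
#' w <- make_csf_waveform(32, peak_up = 1, peak_down = 1, systolic_fraction = 0.5)
#' max(w); min(w); mean(w)
#' @export
make_csf_waveform <- function(n_phases = 32, peak_up = 1.5, peak_down = 2.4,
                              systolic_fraction = 0.45) {
  if (!is.numeric(n_phases) || n_phases < 8 || n_phases != round(n_phases)) {
    abort("`n_phases` must be an integer >= 8.", class = "csfflow_config_error")
  }
  check_number(peak_up, "peak_up", min = 0, strict_min = TRUE)
  check_number(peak_down, "peak_down", min = 0, strict_min = TRUE)
  check_number(systolic_fraction, "systolic_fraction",
               min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)

  t <- (seq_len(n_phases) - 0.5) / n_phases
  sys <- t < systolic_fraction
  if (!any(sys) || all(sys)) {
    abort("`systolic_fraction` leaves an empty lobe at this `n_phases`.",
          class = "csfflow_config_error")
  }
  v <- numeric(n_phases)
  v[sys] <- -sin(pi * t[sys] / systolic_fraction)
  v[!sys] <- sin(pi * (t[!sys] - systolic_fraction) / (1 - systolic_fraction))
  v[sys] <- v[sys] * (peak_down / max(-v[sys]))
  v[!sys] <- v[!sys] * (peak_up / max(v[!sys]))
  v
}

#' Pulsatile venous velocity waveform
#'
#' A single positive velocity pulse per cardiac cycle — a raised-cosine bump
#' whose onset lags the start of the cycle — emulating epidural venous
#' plexus voxels. The pulse is pulsatile at the cardiac period but distinct
#' from CSF in shape and timing, so its zero-lag correlation with the
#' biphasic CSF waveform is low and pulsatility-based segmentation must
#' reject it. At the defaults (onset 0.25 cycle, width 0.3 cycle) the NCC
#' against the default CSF waveform is about -0.23.
#'
#' @inheritParams make_csf_waveform
#' @param peak Peak venous velocity in cm/s (> 0).
#' @param phase_lag Onset of the pulse as a fraction of the cycle.
#' @param width Duration of the pulse as a fraction of the cycle, in (0, 1].
#' @return Numeric vector of length `n_phases` in cm/s, maximum equal to
#'   `peak`.
#' @export
make_venous_waveform <- function(n_phases = 32, peak = 1, phase_lag = 0.25,
                                 width = 0.3) {
  if (!is.numeric(n_phases) || n_phases < 8 || n_phases != round(n_phases)) {
    abort("`n_phases` must be an integer >= 8.", class = "csfflow_config_error")
  }
  check_number(peak, "peak", min = 0, strict_min = TRUE)
  check_number(width, "width", min = 0, max = 1, strict_min = TRUE)
  t <- (seq_len(n_phases) - 0.5) / n_phases
  s <- (t - phase_lag) %% 1
  w <- ifelse(s < width, sin(pi * s / width)^2, 0)
  if (max(w) == 0) {
    abort("Pulse too narrow to be sampled at this `n_phases`.",
          class = "csfflow_config_error")
  }
  w * (peak / max(w))
}
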