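#' Extract per-voxel velocity waveforms from a box
#'
#' Pulls the length-T velocity trace of every voxel inside a bounding box,
#' in deterministic row-major order (row slowest, column fastest).
#'
#' @param vel A `velocity_series`.
#' @param box A [bounding_box()] within the image.
#' @return A `waveform_matrix`: `traces` (`V x T`), `coords` (tibble of
#'   1-based `row`, `col` matching the trace rows), `box`, `image_dim` and
#'   `n_phases`.
#' @export
extract_waveforms <- function(vel, box) {
  stopifnot(inherits(vel, "velocity_series"), inherits(box, "bounding_box"))
  d <- dim(vel$velocity)
  check_box_inside(box, H = d[2], W = d[3])
  rows <- box_rows(box); cols <- box_cols(box)
  sub <- vel$velocity[, rows, cols, drop = FALSE] # T x h x w
  traces <- matrix(aperm(sub, c(3, 2, 1)), nrow = box$w * box$h,
                   ncol = d[1])
  structure(
    list(
      traces = traces,
      coords = tibble(row = rep(rows, each = box$w),
                      col = rep(cols, times = box$h)),
      box = box, image_dim = d[2:3], n_phases = d[1],
      pixel_spacing = vel$pixel_spacing, rr_duration = vel$rr_duration
    ),
    class = "waveform_matrix"
  )
}

#' Zero-lag normalized cross-correlation
#'
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`, bounded in `[-1, 1]`. No lag search is performed:
#' gated cine series are phase-locked to the cardiac cycle.
#'
#' @param x,y Numeric vectors of equal length with nonzero variance.
#' @return The correlation in `[-1, 1]`.
#' @examples
#' ncc(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
ncc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "csfflow_config_error")
  }
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    abort("Zero-variance input: correlation is undefined.",
          class = "csfflow_degenerate_error")
  }
  sum(xc * yc) / den
}

# Fraction of a (centered) component's spectral power in the first
# `n_harmonics` cardiac harmonics of the gated cycle.
pulsatility_score <- function(s, n_harmonics = 2) {
  T <- length(s)
  pw <- Mod(fft(s - mean(s)))^2
  total <- sum(pw[-1])
  if (total == 0) return(0)
  idx <- unique(c(1 + seq_len(n_harmonics), T + 1 - seq_len(n_harmonics)))
  idx <- idx[idx >= 2 & idx <= T]
  sum(pw[idx]) / total
}

#' CSF reference waveform by temporal ICA
#'
#' Decomposes the canal-box voxel traces into `k` temporal independent
#' components (fixed-point ICA on whitened, temporally centered data), under
#' the working assumption that the canal signal mixes three sources: CSF,
#' blood, and static tissue. Components are scored by pulsatility — the
#' fraction of spectral power in the first two cardiac harmonics — and kept
#' if the score reaches `pulsatility_floor` and the component agrees with the
#' top-scoring one (`|NCC| >= ncc_min`). Retained components are sign-aligned
#' to the top component and averaged; the preliminary reference is then the
#' loading-weighted average of the voxel signals explained by that source —
#' a reconstruction in data space that denoises the short (length-T) source
#' estimate — normalized to zero mean and unit SD.
#' Orientation is fixed so the reference correlates positively with the mean
#' trace of the 25% most pulsatile voxels (cranial-positive convention).
#'
#' @param wm A `waveform_matrix` from [extract_waveforms()].
#' @param k Number of temporal components (default 3); reduced automatically
#'   to the numerical rank of the data.
#' @param pulsatility_floor Minimum pulsatility score for a component to
#'   survive filtering.
#' @param ncc_min Minimum `|NCC|` to the top-scoring component.
#' @param n_harmonics Cardiac harmonics counted as pulsatile power.
#' @param seed Seed for the random orthogonal ICA initialization; on
#'   non-convergence the decomposition is retried (up to `max_retries`
#'   times) with fresh seeds, all recorded in the result.
#' @param max_retries Reseeded retries allowed on ICA non-convergence.
#' @param maxit,tol Fixed-point iteration budget and tolerance.
#' @return A `reference_waveform`: `trace` (zero mean, unit SD, length T),
#'   `retained_component_ids`, per-component `scores`, `k_used`, `attempts`.
#' @export
ica_reference <- function(wm, k = 3, pulsatility_floor = 0.5, ncc_min = 0.5,
                          n_harmonics = 2, seed = 1, max_retries = 3,
                          maxit = 200, tol = 1e-6) {
  stopifnot(inherits(wm, "waveform_matrix"))
  X <- wm$traces
  keep_rows <- apply(X, 1, function(r) sd(r) > 0)
  X <- X[keep_rows, , drop = FALSE]
  V <- nrow(X); T <- ncol(X)
  if (V <= k) {
    abort(sprintf("Need more voxel traces (%d) than components (%d).", V, k),
          class = "csfflow_config_error")
  }
  Xc <- X - rowMeans(X)

  sv <- svd(Xc, nu = 0, nv = 0)$d
  k_eff <- min(k, sum(sv > max(sv) * 1e-8), T - 1)
  if (k_eff < 1) {
    abort("Canal traces carry no temporal signal.",
          class = "csfflow_degenerate_error")
  }

  attempts <- 0
  converged <- FALSE
  srcs <- NULL
  if (k_eff == 1) {
    # One-component limit: the principal temporal component is the source.
    attempts <- 1
    converged <- TRUE
    srcs <- matrix(svd(Xc, nu = 0, nv = 1)$v[, 1], nrow = 1)
  } else {
    for (a in seq_len(max_retries + 1)) {
      attempts <- a
      set.seed(seed + a - 1)
      R0 <- qr.Q(qr(matrix(rnorm(k_eff^2), k_eff)))
      fit <- ica::icafast(t(Xc), nc = k_eff, center = TRUE,
                          maxit = maxit, tol = tol, Rmat = R0)
      srcs <- t(fit$S) # k_eff x T temporal sources
      if (fit$iter < maxit) {
        converged <- TRUE
        break
      }
    }
  }

  # Score even a non-converged iterate: structureless input should be
  # diagnosed as degenerate signal, not as an optimizer failure.
  scores <- apply(srcs, 1, pulsatility_score, n_harmonics = n_harmonics)
  keep <- which(scores >= pulsatility_floor)
  if (length(keep) == 0) {
    abort(sprintf(
      "No ICA component is pulsatile (max score %.3f < floor %.2f): degenerate signal.",
      max(scores), pulsatility_floor),
      class = "csfflow_degenerate_error")
  }
  if (!converged) {
    abort(sprintf(
      "ICA did not converge within %d iterations after %d seeded attempts.",
      maxit, attempts),
      class = "csfflow_convergence_error")
  }
  top <- keep[which.max(scores[keep])]
  sims <- vapply(keep, function(i) ncc(srcs[i, ], srcs[top, ]), numeric(1))
  sel <- keep[abs(sims) >= ncc_min]
  signs <- sign(sims[abs(sims) >= ncc_min])

  aligned <- srcs[sel, , drop = FALSE] * signs
  src <- colMeans(aligned)
  src <- src - mean(src)
  # Preliminary reference: average of the retained voxel signals, weighted
  # by their loading on the selected source. Reconstructing in data space
  # denoises the short (length-T) source estimate considerably.
  w <- as.vector(Xc %*% src) / sum(src^2)
  ref <- as.vector(t(Xc) %*% w)
  ref <- (ref - mean(ref)) / sd(ref)

  # Cranial-positive orientation via the most pulsatile voxels.
  sds <- apply(X, 1, sd)
  hot <- sds >= quantile(sds, 0.75, names = FALSE)
  mv <- colMeans(X[hot, , drop = FALSE])
  if (sd(mv) > 0 && ncc(ref, mv) < 0) ref <- -ref

  structure(
    list(trace = ref, retained_component_ids = sel, scores = scores,
         k_requested = k, k_used = k_eff, attempts = attempts,
         n_phases = T),
    class = "reference_waveform"
  )
}

#' @export
print.reference_waveform <- function(x, ...) {
  cat(sprintf(
    "<reference_waveform> T=%d, %d/%d components retained (scores %s), %d ICA attempt(s)\n",
    x$n_phases, length(x$retained_component_ids), length(x$scores),
    paste(sprintf("%.2f", x$scores), collapse = ", "), x$attempts))
  invisible(x)
}

#' Pulsatility-based segmentation (NCC thresholding)
#'
#' Classifies each canal-box voxel as flowing CSF when the zero-lag NCC
#' between its velocity trace and the reference waveform reaches the
#' threshold (ties at exactly the threshold are included). Zero-variance
#' voxels have undefined correlation and are excluded. The full NCC map is
#' returned so threshold sweeps need no recomputation.
#'
#' @param wm A `waveform_matrix`.
#' @param ref A `reference_waveform` (or any length-T numeric trace).
#' @param threshold NCC inclusion threshold in `(-1, 1]`; 0.5 is the
#'   established optimum for this segmentation family.
#' @return A `csf_mask`: logical `mask` (`H x W`), `ncc_map` (`H x W`, `NA`
#'   outside the box and at zero-variance voxels), `threshold`, `box`.
#' @export
pubs_mask <- function(wm, ref, threshold = 0.5) {
  stopifnot(inherits(wm, "waveform_matrix"))
  check_number(threshold, "threshold", min = -1, max = 1, strict_min = TRUE)
  trace <- if (inherits(ref, "reference_waveform")) ref$trace else ref
  if (length(trace) != wm$n_phases) {
    abort("Reference length does not match the number of cardiac phases.",
          class = "csfflow_config_error")
  }
  Xc <- wm$traces - rowMeans(wm$traces)
  rc <- trace - mean(trace)
  den <- sqrt(rowSums(Xc^2) * sum(rc^2))
  vals <- as.vector(Xc %*% rc) / den
  vals[den == 0] <- NA_real_

  ncc_map <- matrix(NA_real_, wm$image_dim[1], wm$image_dim[2])
  ncc_map[cbind(wm$coords$row, wm$coords$col)] <- vals
  mask <- !is.na(ncc_map) & ncc_map >= threshold
  structure(
    list(mask = mask, ncc_map = ncc_map, threshold = threshold,
         box = wm$box),
    class = "csf_mask"
  )
}

#' @export
print.csf_mask <- function(x, ...) {
  cat(sprintf("<csf_mask> %d voxels at NCC >= %.2f (box %gx%g)\n",
              sum(x$mask), x$threshold, x$box$w, x$box$h))
  invisible(x)
}

#' Dice overlap between two masks
#'
#' @param a,b Logical matrices (or `csf_mask` objects) of equal dimension.
#' @return `2|A∩B| / (|A| + |B|)`.
#' @export
dice <- function(a, b) {
  if (inherits(a, "csf_mask")) a <- a$mask
  if (inherits(b, "csf_mask")) b <- b$mask
  2 * sum(a & b) / (sum(a) + sum(b))
}
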