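# Internal helpers shared across modules.

# Wrap phase angles into [-pi, pi).
wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

# 2D polynomial basis over an H x W pixel grid, row index fastest
# (column-major, matching as.vector() of an H x W matrix). Coordinates are
# normalized to [0, 1] so coefficients are comparable across image sizes.
# degree 0 -> intercept; degree 1 -> 1, x, y; degree 2 adds x^2, xy, y^2; ...
poly_basis <- function(H, W, degree) {
  stopifnot(degree >= 0)
  x <- rep((seq_len(W) - 1) / max(W - 1, 1), each = H)
  y <- rep((seq_len(H) - 1) / max(H - 1, 1), times = W)
  cols <- list(`(Intercept)` = rep(1, H * W))
  if (degree >= 1) {
    for (d in seq_len(degree)) {
      for (j in 0:d) {
        cols[[paste0("x", d - j, "y", j)]] <- x^(d - j) * y^j
      }
    }
  }
  do.call(cbind, cols)
}

# Number of coefficients of the 2D polynomial of a given degree.
poly_n_coef <- function(degree) (degree + 1) * (degree + 2) / 2

# Degree implied by a background coefficient vector (1, 3, 6, 10, ... terms).
poly_degree_from_coef <- function(coef) {
  for (d in 0:6) {
    if (length(coef) == poly_n_coef(d)) return(d)
  }
  abort(
    "`background_coef` must have 1, 3, 6, ... entries (a full 2D polynomial).",
    class = "csfflow_config_error"
  )
}

# Per-voxel temporal standard deviation of a T x H x W array, as an H x W
# matrix. Computed from moments so it stays a single pass over the stack.
temporal_sd_map <- function(stack) {
  d <- dim(stack)
  m <- matrix(stack, nrow = d[1])
  mu <- colMeans(m)
  v <- pmax(colMeans(m^2) - mu^2, 0) * d[1] / (d[1] - 1)
  matrix(sqrt(v), nrow = d[2], ncol = d[3])
}

# Canonical FlowMetrics field names, in reporting order.
metric_fields <- function() {
  c(
    "upward_mean_flow", "downward_mean_flow", "summation_mean_flow",
    "upward_peak_flow", "downward_peak_flow", "summation_peak_flow",
    "upward_total_flow", "downward_total_flow", "absolute_stroke_volume",
    "net_output"
  )
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    abort(
      sprintf("`%s` must be a single finite number in %s%s, %s%s.",
              name, if (strict_min) "(" else "[", format(min),
              format(max), if (strict_max) ")" else "]"),
      class = "csfflow_config_error"
    )
  }
  invisible(x)
}
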