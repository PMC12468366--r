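test_that("CSF waveform hits its peaks exactly and is balanced when symmetric", {
  w <- make_csf_waveform(32, peak_up = 1, peak_down = 1,
                         systolic_fraction = 0.5)
  expect_equal(max(w), 1.0)
  expect_equal(min(w), -1.0)
  expect_equal(mean(w), 0, tolerance = 1e-12)

  w2 <- make_csf_waveform(32, peak_up = 2, peak_down = 3)
  expect_equal(max(w2), 2.0)
  expect_equal(min(w2), -3.0)

  # asymmetric lobe fractions still hit sampled extrema exactly
  w3 <- make_csf_waveform(20, peak_up = 0.7, peak_down = 1.9,
                          systolic_fraction = 0.37)
  expect_equal(max(w3), 0.7)
  expect_equal(min(w3), -1.9)
  expect_length(w3, 20)

  expect_error(make_csf_waveform(32, peak_up = 0), class = "csfflow_config_error")
  expect_error(make_csf_waveform(32, peak_down = -1), class = "csfflow_config_error")
  expect_error(make_csf_waveform(4), class = "csfflow_config_error")
})

test_that("venous waveform is a low-correlation pulsatile confounder", {
  v <- make_venous_waveform(32, peak = 1.3)
  expect_equal(max(v), 1.3)
  expect_gte(min(v), 0)
  # distinct from CSF: |NCC| well below the 0.5 segmentation threshold
  expect_lt(abs(ncc(make_csf_waveform(32), v)), 0.35)
})

test_that("phase encoding round-trips exactly on a noise-free scene", {
  cfg <- scene_config(seed = 3, noise_sd = 0, venous_fraction = 0,
                      background_coef = 0, n_acquisitions = 1)
  sc <- render_scene(cfg)
  vel <- phase_to_velocity(sc$series[[1]])
  idx <- which(sc$truth$csf_mask)
  V <- matrix(vel$velocity, nrow = cfg$n_phases)
  for (j in idx[c(1, 50, length(idx))]) {
    expect_equal(V[, j], sc$truth$true_waveform, tolerance = 1e-12)
  }
  expect_true(all(abs(V[, j]) <= cfg$venc))
  # static tissue decodes to exactly zero
  expect_equal(max(abs(V[, which(!sc$truth$csf_mask)[1:100]])), 0)
})

test_that("constant background offset decodes to venc * c / pi at static voxels", {
  c0 <- 0.12
  cfg <- scene_config(seed = 3, noise_sd = 0, venous_fraction = 0,
                      background_coef = c0, n_acquisitions = 1)
  sc <- render_scene(cfg)
  vel <- phase_to_velocity(sc$series[[1]])
  static <- which(!sc$truth$csf_mask)[1:50]
  V <- matrix(vel$velocity, nrow = cfg$n_phases)
  expect_equal(as.vector(V[, static]),
               rep(cfg$venc * c0 / pi, 50 * cfg$n_phases),
               tolerance = 1e-12)
})

test_that("velocity aliasing is rejected unless wrapping is enabled", {
  expect_error(
    render_scene(scene_config(venc = 2, csf_peak_down = 2.4, seed = 1)),
    class = "csfflow_aliasing_error"
  )
  sc <- render_scene(scene_config(venc = 2, csf_peak_down = 2.4,
                                  allow_wrap = TRUE, seed = 1,
                                  noise_sd = 0))
  expect_s3_class(sc$series[[1]], "cine_series")
})

test_that("ground truth satisfies its structural invariants", {
  sc <- scene_fixture()
  tr <- sc$truth
  expect_false(any(tr$csf_mask & tr$venous_mask))
  inside <- matrix(FALSE, nrow(tr$csf_mask), ncol(tr$csf_mask))
  inside[(tr$canal_bbox$y + 1):(tr$canal_bbox$y + tr$canal_bbox$h),
         (tr$canal_bbox$x + 1):(tr$canal_bbox$x + tr$canal_bbox$w)] <- TRUE
  expect_true(all(inside[tr$csf_mask]))
  expect_true(all(inside[tr$venous_mask]))
  # generator metrics obey the same identities as the metric module
  m <- tr$true_metrics
  expect_equal(m$summation_mean_flow, m$upward_mean_flow + m$downward_mean_flow)
  expect_equal(m$absolute_stroke_volume,
               m$upward_total_flow + m$downward_total_flow)
  expect_equal(m$absolute_stroke_volume, sum(abs(tr$true_flow_curve)))
  expect_length(sc$series, 3)
})

test_that("fixed seeds give bit-identical scenes and cohorts", {
  a <- render_scene(scene_config(seed = 11))
  b <- render_scene(scene_config(seed = 11))
  expect_identical(a$series[[2]]$phase, b$series[[2]]$phase)
  expect_identical(a$truth$venous_mask, b$truth$venous_mask)

  spec <- csf_reference_cohorts()[csf_reference_cohorts()$cohort == "baseline", ]
  c1 <- simulate_metric_cohort(spec, seed = 9)
  c2 <- simulate_metric_cohort(spec, seed = 9)
  expect_identical(c1, c2)
})

test_that("cohort simulation honors its distributional contract", {
  spec <- tibble::tibble(
    group = rep(c("A", "B"), each = 2),
    n = rep(c(5L, 4L), each = 2),
    metric = rep(c("upward_peak_flow", "downward_peak_flow"), 2),
    mean = c(2, 3, 2, 3), sd = c(0, 0, 0, 0)
  )
  z <- simulate_metric_cohort(spec, seed = 1)
  expect_equal(nrow(z), 9)
  expect_true(all(z$upward_peak_flow == 2))
  expect_true(all(z$downward_peak_flow == 3))

  # truncation keeps physical metrics non-negative even at harsh SDs
  spec2 <- tibble::tibble(group = "A", n = 500L,
                          metric = "upward_mean_flow", mean = 0.1, sd = 1)
  z2 <- simulate_metric_cohort(spec2, seed = 2)
  expect_true(all(z2$upward_mean_flow >= 0))

  expect_error(simulate_metric_cohort(data.frame(group = "A")),
               class = "csfflow_config_error")
  spec3 <- spec; spec3$n <- 1L
  expect_error(simulate_metric_cohort(spec3), class = "csfflow_config_error")
})

test_that("identical group specs give chance-level discrimination", {
  spec <- tibble::tibble(
    group = c("A", "B"), n = c(20L, 20L),
    metric = "upward_peak_flow", mean = 1.5, sd = 0.5
  )
  # unfolded AUC via the U identity (roc() auto-orients, which would fold
  # the null distribution above 0.5)
  aucs <- vapply(1:200, function(s) {
    z <- simulate_metric_cohort(spec, seed = s)
    a <- z$upward_peak_flow[z$group == "A"]
    b <- z$upward_peak_flow[z$group == "B"]
    1 - mann_whitney(a, b)$U / (length(a) * length(b))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
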