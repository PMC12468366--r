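# Shared fixtures, built once per test run. The default scene is the study
# condition every seeded DERIVED check runs against: 64 x 64 px, 32 phases,
# venc 10 cm/s, annular CSF with venous confounders and noise_sd 0.2 cm/s,
# three acquisitions, seed 42.

.fixtures <- new.env(parent = emptyenv())

scene_fixture <- function() {
  if (is.null(.fixtures$scene)) {
    .fixtures$scene <- render_scene(scene_config(seed = 42))
  }
  .fixtures$scene
}

subject_fixture <- function() {
  if (is.null(.fixtures$subject)) {
    .fixtures$subject <- run_subject(
      pipeline_config(scene = scene_config(seed = 42), seed = 42)
    )
  }
  .fixtures$subject
}

# First-acquisition segmentation intermediates on the default scene.
segmentation_fixture <- function() {
  if (is.null(.fixtures$seg)) {
    sc <- scene_fixture()
    s <- sc$series[[1]]
    vel <- phase_to_velocity(s)
    box <- detect_canal(s)
    velc <- correct_background(vel, exclude_box = box)
    wm <- extract_waveforms(velc, box)
    ref <- ica_reference(wm, seed = 42)
    .fixtures$seg <- list(scene = sc, vel = velc, box = box, wm = wm,
                          ref = ref)
  }
  .fixtures$seg
}

# Minimal hand-built velocity series: constant velocity v0 everywhere.
flat_velocity_series <- function(v0, T = 4, H = 10, W = 10,
                                 pixel_spacing = 1, rr = 1) {
  structure(
    list(velocity = array(v0, dim = c(T, H, W)), venc = 10, n_phases = T,
         pixel_spacing = pixel_spacing, rr_duration = rr,
         acquisition_id = "manual", background_corrected = FALSE),
    class = "velocity_series"
  )
}
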