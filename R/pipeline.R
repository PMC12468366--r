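#' Pipeline configuration
#'
#' Bundles every tunable of a subject-level run: the input (synthetic scene
#' or on-disk series), detector mode, NCC threshold, background model,
#' acquisition-averaging mode and seed. The configuration hash is embedded
#' in every report so runs are auditable.
#'
#' @param scene A [scene_config()] for synthetic input, or `NULL`.
#' @param paths Character vector of series directories (1-3 acquisitions),
#'   or `NULL`.
#' @param dialect Dialect for [read_series()] when `paths` is used.
#' @param detector `"builtin"` (pulsatility saliency) or `"external"`.
#' @param external_box [bounding_box()] used when `detector = "external"`.
#' @param ncc_threshold Segmentation threshold in `(-1, 1]` (default 0.5).
#' @param background_degree Background polynomial degree (default 1).
#' @param static_quantile Temporal-SD quantile for static-voxel selection.
#' @param averaging `"metrics"` (compute per acquisition, then average;
#'   default) or `"waveform"` (average flow curves, then compute metrics).
#' @param ica_k,pulsatility_floor,ica_ncc_min ICA settings, see
#'   [ica_reference()].
#' @param time_integrated Report per-cycle totals integrated in time.
#' @param margin,smooth_sigma Detector settings, see [detect_canal()].
#' @param output_dir Optional directory for report artifacts.
#' @param seed Integer seed governing every stochastic stage.
#' @param verbose Log stage progress via `message()`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(scene = NULL, paths = NULL, dialect = NULL,
                            detector = c("builtin", "external"),
                            external_box = NULL, ncc_threshold = 0.5,
                            background_degree = 1, static_quantile = 0.3,
                            averaging = c("metrics", "waveform"),
                            ica_k = 3, pulsatility_floor = 0.5,
                            ica_ncc_min = 0.5, time_integrated = FALSE,
                            margin = 2, smooth_sigma = 1.5,
                            output_dir = NULL, seed = 1, verbose = FALSE) {
  detector <- match.arg(detector)
  averaging <- match.arg(averaging)
  if (is.null(scene) == is.null(paths)) {
    abort("Provide exactly one of `scene` or `paths`.",
          class = "csfflow_config_error")
  }
  check_number(ncc_threshold, "ncc_threshold", min = -1, max = 1,
               strict_min = TRUE)
  if (detector == "external" && !inherits(external_box, "bounding_box")) {
    abort("`external_box` is required when detector = \"external\".",
          class = "csfflow_config_error")
  }
  structure(
    list(
      scene = scene, paths = paths, dialect = dialect, detector = detector,
      external_box = external_box, ncc_threshold = ncc_threshold,
      background_degree = background_degree,
      static_quantile = static_quantile, averaging = averaging,
      ica_k = ica_k, pulsatility_floor = pulsatility_floor,
      ica_ncc_min = ica_ncc_min, time_integrated = time_integrated,
      margin = margin, smooth_sigma = smooth_sigma,
      output_dir = output_dir, seed = seed, verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Run the full subject-level pipeline
#'
#' Executes, per acquisition: read (or render) -> phase decoding -> canal
#' detection -> background correction (static voxels outside the canal box)
#' -> ICA reference waveform -> pulsatility-based segmentation -> flow curve
#' -> metrics; acquisitions are then combined. Every stage is deterministic
#' given the configuration seed. Stage failures propagate with the stage
#' name attached.
#'
#' @param config A [pipeline_config()].
#' @return A `subject_result`: combined `metrics`, per-acquisition artifacts
#'   (`metrics`, `mask`, `flow_curve`, `box`, `reference`), the `config` and
#'   its `config_hash`. If `config$output_dir` is set, a JSON report, flow
#'   curve CSVs, mask PNGs and NCC maps are written there.
#' @examples
#' \donttest{
#' res <- run_subject(pipeline_config(scene = scene_config(seed = 7), seed = 7))
#' res$metrics
#' }
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  say <- function(...) if (config$verbose) message(sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        sprintf("Stage `%s` failed: %s", name, conditionMessage(e)),
        class = c("csfflow_stage_error", class(e)[1]),
        parent = e
      )
    })
  }

  series_list <- if (!is.null(config$scene)) {
    sc <- config$scene
    if (is.null(sc$seed)) sc$seed <- config$seed
    stage("render", render_scene(sc)$series)
  } else {
    if (length(config$paths) < 1 || length(config$paths) > 3) {
      abort("Between 1 and 3 acquisition paths are expected.",
            class = "csfflow_config_error")
    }
    stage("read", lapply(config$paths, read_series,
                         dialect = config$dialect))
  }

  acq <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    say("acquisition %d/%d (%s)", i, length(series_list), s$acquisition_id)
    vel <- stage("decode", phase_to_velocity(s))
    box <- stage("detect", detect_canal(
      s, margin = config$margin, smooth_sigma = config$smooth_sigma,
      mode = config$detector, external_box = config$external_box))
    velc <- stage("background", correct_background(
      vel, degree = config$background_degree, exclude_box = box,
      static_quantile = config$static_quantile))
    wm <- stage("extract", extract_waveforms(velc, box))
    ref <- stage("ica", ica_reference(
      wm, k = config$ica_k, pulsatility_floor = config$pulsatility_floor,
      ncc_min = config$ica_ncc_min, seed = config$seed + i))
    say("  ICA: %d attempt(s), components %s retained", ref$attempts,
        paste(ref$retained_component_ids, collapse = ","))
    mask <- stage("pubs", pubs_mask(wm, ref, config$ncc_threshold))
    fc <- stage("flow", flow_curve(velc, mask))
    acq[[i]] <- list(
      metrics = compute_metrics(fc, config$time_integrated),
      mask = mask, flow_curve = fc, box = box, reference = ref,
      acquisition_id = s$acquisition_id
    )
  }

  metrics <- if (config$averaging == "metrics" || length(acq) == 1) {
    combine_acquisitions(lapply(acq, `[[`, "metrics"))
  } else {
    qbar <- rowMeans(vapply(acq, function(a) a$flow_curve$q,
                            numeric(acq[[1]]$flow_curve$n_phases)))
    fc1 <- acq[[1]]$flow_curve
    compute_metrics(new_flow_curve(qbar, fc1$pixel_area, fc1$n_phases,
                                   fc1$rr_duration),
                    config$time_integrated)
  }

  # Hash covers the scientific configuration only, so identical analyses
  # produce identical reports regardless of where they are written.
  cfg_h <- unclass(config)
  cfg_h$output_dir <- NULL
  cfg_h$verbose <- NULL
  result <- structure(
    list(
      metrics = metrics, acquisitions = acq, config = config,
      config_hash = hash(cfg_h), n_acquisitions = length(acq)
    ),
    class = "subject_result"
  )
  if (!is.null(config$output_dir)) write_subject_report(result)
  result
}

write_subject_report <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  report <- list(
    config_hash = result$config_hash,
    seed = cfg$seed,
    parameters = list(
      detector = cfg$detector, ncc_threshold = cfg$ncc_threshold,
      background_degree = cfg$background_degree,
      averaging = cfg$averaging, ica_k = cfg$ica_k,
      pulsatility_floor = cfg$pulsatility_floor,
      time_integrated = cfg$time_integrated
    ),
    metrics = unclass(result$metrics),
    acquisitions = lapply(result$acquisitions, function(a) {
      list(
        acquisition_id = a$acquisition_id,
        box = unclass(a$box),
        n_mask_voxels = sum(a$mask$mask),
        ica_attempts = a$reference$attempts,
        ica_retained = a$reference$retained_component_ids,
        metrics = unclass(a$metrics)
      )
    })
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (a in result$acquisitions) {
    id <- a$acquisition_id
    write.csv(
      data.frame(time_s = a$flow_curve$times, flow_ml_s = a$flow_curve$q),
      file.path(dir, sprintf("flow_curve_%s.csv", id)), row.names = FALSE
    )
    EBImage::writeImage(a$mask$mask * 1,
                        file.path(dir, sprintf("mask_%s.png", id)))
    nccmap <- a$mask$ncc_map
    nccmap[is.na(nccmap)] <- 0
    RNifti::writeNifti(nccmap, file.path(dir, sprintf("ncc_%s.nii.gz", id)))
  }
  invisible(dir)
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %d acquisition(s), hash %s\n",
              x$n_acquisitions, substr(x$config_hash, 1, 10)))
  print(x$metrics)
  invisible(x)
}

#' Run the cohort-level analysis
#'
#' Produces the group-comparison table (mean, SD, Mann-Whitney p per metric)
#' and the ROC table (AUC, Youden cutoff, sensitivity/specificity per
#' metric) for any two labeled groups. The same schema serves the baseline
#' patient-vs-volunteer contrast and the treatment-response contrast. The
#' input can be subject-level data or a group-summary spec (columns `mean`
#' and `sd`), in which case a cohort is first simulated.
#'
#' @param subjects Subject-level tibble (group column + metric columns), or
#'   a spec accepted by [simulate_metric_cohort()].
#' @param group Name of the group column.
#' @param positive Group treated as the ROC positive class; defaults to the
#'   second level.
#' @param metrics Metric columns; defaults to canonical fields present.
#' @param seed Seed used only when `subjects` is a spec to simulate.
#' @param output_dir Optional directory for `comparison.csv` / `roc.csv`.
#' @return A `cohort_result` with `comparison` and `roc` tibbles and the
#'   subject table used.
#' @export
run_cohort <- function(subjects, group = "group", positive = NULL,
                       metrics = NULL, seed = NULL, output_dir = NULL) {
  if (all(c("mean", "sd", "metric", "n") %in% names(subjects))) {
    subjects <- simulate_metric_cohort(subjects, seed = seed)
  }
  g <- factor(subjects[[group]])
  if (any(table(g) < 2) || nlevels(droplevels(g)) != 2) {
    abort("Need exactly two groups with >= 2 subjects each.",
          class = "csfflow_config_error")
  }
  comparison <- cohort_compare(subjects, group = group, metrics = metrics)
  roc_tab <- cohort_roc(subjects, group = group, positive = positive,
                        metrics = metrics)
  out <- structure(
    list(comparison = comparison, roc = roc_tab, subjects = subjects,
         n = table(droplevels(g))),
    class = "cohort_result"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(comparison, file.path(output_dir, "comparison.csv"),
              row.names = FALSE)
    write.csv(roc_tab, file.path(output_dir, "roc.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n), x$n), collapse = " vs ")))
  cat("\nGroup comparison:\n"); print(x$comparison)
  cat("\nROC:\n"); print(x$roc)
  invisible(x)
}
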