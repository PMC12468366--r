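# csfflow

Automated quantification of pulsatile cerebrospinal fluid (CSF) flow at the
upper cervical spine (C2) from ECG-gated cine phase-contrast MRI (PC-MRI).

Spinal CSF leaks (spontaneous intracranial hypotension, SIH) globally
depress the cardiac-driven oscillation of CSF through the cervical
subarachnoid space, and its recovery after an epidural blood patch predicts
treatment response. Measuring that oscillation by hand — drawing a region
of interest on a noisy velocity map shared with pulsatile epidural veins —
is slow and operator-dependent. `csfflow` implements the automated
alternative for radiology and neuroimaging researchers:

1. **Canal detection** on the cine stacks: a temporal-pulsatility saliency
   detector (Otsu + connected components) behind a pluggable contract that
   also accepts boxes from any trained detector, with IoU and
   average-precision evaluators.
2. **Background phase correction**: least-squares polynomial fit of the
   static-tissue velocity baseline, subtracted from every frame.
3. **Reference waveform** by temporal ICA over canal voxels, with
   pulsatility-based component filtering.
4. **Pulsatility-based segmentation (PUBS)**: voxel `i` is flowing CSF iff
   `NCC(v_i, ref) >= 0.5`, where `NCC` is the zero-lag normalized
   cross-correlation.
5. **Flow metrics** from the segmented flow curve
   `q[t] = sum_i v_i[t] * A_px` (mL/s, cranial-positive): directional mean,
   peak and per-cycle total flow, absolute stroke volume
   `sum_t |q[t]|`, and net output `sum_t q[t]`, averaged over the three
   consecutive acquisitions.
6. **Cohort statistics**: Mann-Whitney group comparisons, Fisher /
   chi-square tests, and ROC analysis with Youden-optimal cutoffs
   (empirical AUC via the Mann-Whitney identity).

A synthetic cine-scene generator with analytic ground truth (annular CSF
space, lagged venous confounders, polynomial background field, acquisition
noise) makes the whole chain testable without clinical data, and
`simulate_metric_cohort()` reproduces cohort-level analyses from published
group summaries. See the vignette
(`vignettes/csf-flow-quantification.Rmd`) for the model and every design
decision.

## Worked example

```r
library(csfflow)

# Subject-level: three synthetic gated acquisitions, full pipeline
res <- run_subject(pipeline_config(scene = scene_config(seed = 7), seed = 7))
res
#> <subject_result> 3 acquisition(s), hash 1b1a72a218
#> <flow_metrics>
#>   upward_mean_flow         1.37
#>   downward_mean_flow       2.31
#>   summation_mean_flow      3.69
#>   upward_peak_flow         2.2
#>   downward_peak_flow       3.52
#>   summation_peak_flow      5.72
#>   upward_total_flow        24.7
#>   downward_total_flow      32.4
#>   absolute_stroke_volume   57.1
#>   net_output               -7.67
```

The scene's analytic ground-truth stroke volume is 57.11 mL/cycle, so the
end-to-end estimate is within 0.2%. Means and peaks are mL/s; per-cycle
totals are phase-sample sums (mL/cycle) whose directional total/mean
ratios add up to the 32 acquired cardiac phases. The negative net output
says this scene moves slightly more CSF caudally than cranially per cycle.
`autoplot()` methods draw the flow curve, the NCC map with the segmented
mask, the reference waveform, and ROC curves; `tidy()`/`glance()` return
tibbles.

```r
# Cohort-level: simulate the published baseline contrast (31 SIH vs 26
# healthy volunteers) and reproduce the table schemas
spec <- dplyr::filter(csf_reference_cohorts(), cohort == "baseline")
co <- run_cohort(spec, seed = 7, positive = "HV")
dplyr::select(tidy(co), metric, p_value, auc, cutoff, sensitivity, specificity)
#> # A tibble: 9 × 6
#>   metric                  p_value   auc cutoff sensitivity specificity
#> 1 upward_mean_flow     2.81e-3    0.732  0.781        88.5        58.1
#> 2 downward_mean_flow   1.16e-6    0.877  1.47         73.1        90.3
#> 3 summation_mean_flow  3.22e-5    0.823  2.34         76.9        83.9
#> 4 upward_peak_flow     1.61e-4    0.793  1.77         57.7        96.8
#> 5 downward_peak_flow   1.58e-5    0.835  2.82         61.5        93.5
#> 6 summation_peak_flow  1.95e-4    0.789  4.24         65.4        83.9
#> 7 upward_total_flow    7.64e-3    0.707 13.9          84.6        51.6
#> 8 downward_total_flow  1.18e-3    0.752 17.2          69.2        80.6
#> 9 absolute_stroke_volume 9.67e-3  0.701 34.4          69.2        71.0
```

Every metric separates the groups (all p < 0.01 in this replicate), with
AUCs in the 0.70-0.88 range expected from the published effect sizes.

A thin CLI mirrors these entry points
(`inst/cli/csfflow simulate|subject|cohort`).

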