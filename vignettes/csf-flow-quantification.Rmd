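---
title: "Quantifying spinal CSF flow from cine phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal CSF flow from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfflow)
```

## The measurement problem

Cerebrospinal fluid (CSF) oscillates through the spinal subarachnoid space
with every heartbeat: caudally during cardiac systole, cranially during
diastole. ECG-gated cine phase-contrast MRI (PC-MRI) at the C2 vertebral
level captures this as a stack of `T` image pairs spanning one R-R
interval — a magnitude image and a velocity-encoded phase image per cardiac
phase. The phase of a voxel is proportional to its through-plane velocity,

$$\varphi = \pi \, v / v_{enc}, \qquad v = v_{enc} \, \varphi / \pi,$$

where the velocity-encoding limit `venc` (here 10-15 cm/s) is the aliasing
boundary. In conditions of CSF hypovolemia — notably spontaneous
intracranial hypotension (SIH), caused by a spinal CSF leak — the
pulsatile flow at C2 is globally depressed, and its recovery after an
epidural blood patch (EBP) carries prognostic information. Quantifying
that flow by hand is slow and operator-dependent, especially where enlarged
epidural venous plexuses add confounding pulsatile signal. `csfflow`
implements an automated pipeline:

1. **Canal detection** on the magnitude/velocity stacks (a pluggable
   detector; the built-in one is classical).
2. **Background phase correction** against static tissue.
3. **Reference waveform** estimation by temporal independent component
   analysis (ICA) over the canal voxels.
4. **Pulsatility-based segmentation (PUBS)**: a voxel is flowing CSF iff
   the zero-lag normalized cross-correlation (NCC) between its velocity
   waveform and the reference reaches a threshold (default 0.5).
5. **Flow metrics** from the segmented flow curve, averaged over three
   consecutive acquisitions.
6. **Cohort statistics**: Mann-Whitney comparisons, Fisher/chi-square for
   nominal variables, and ROC analysis with Youden-optimal cutoffs.

Everything is testable without clinical data through a synthetic scene
generator with analytic ground truth.

## Conventions

* **Sign**: cranial (upward) velocity and flow are positive, caudal
  negative. The convention is fixed globally; the reference waveform is
  oriented so it correlates positively with the most pulsatile voxels.
* **Phase encoding**: radians in `[-pi, pi)`, `phi = pi * v / venc`; a
  configuration whose peak velocity reaches `venc` is rejected with an
  aliasing error unless wrapping is explicitly enabled.
* **Coordinates**: row-major, 0-based, half-open bounding boxes
  (`x`,`y` = column,row origin; `w`,`h` extents).
* **Units**: velocities cm/s, pixel spacing mm, flow mL/s
  (`pixel_area = (spacing/10)^2` cm²), per-cycle totals mL/cycle.

## The flow metrics

Let `q[t]` be the net flow (mL/s) over the segmented CSF voxels at cardiac
phase `t`, `U = {t : q[t] > 0}`, `D = {t : q[t] < 0}`. The ten reported
metrics are

| metric | definition |
|---|---|
| upward/downward mean flow | `mean(q[U])`, `mean(-q[D])` |
| summation of mean flow | sum of the two |
| upward/downward peak flow | `max(q[U])`, `max(-q[D])` |
| summation of peak flow | sum of the two |
| upward/downward total flow | `sum(q[U])`, `sum(-q[D])` |
| absolute stroke volume | `sum(abs(q))` = sum of the totals |
| net output per cycle | `sum(q)` = difference of the totals |

Direction is decided by the sign of the *net per-phase flow*, not per
voxel; phases with `q[t]` exactly 0 belong to neither direction (measure
zero for continuous data). Totals are phase-sample sums labelled
mL/cycle. This convention was adopted because it uniquely reproduces the
ratio structure of the published group tables: each direction's
total/mean ratio is its phase count, so the two ratios sum to the
32 acquired phases — a property that holds for all published group columns
and is enforced by the acceptance checks. A `time_integrated = TRUE`
switch rescales totals by `rr_duration / n_phases` for physically
integrated volumes.

One published cell (the treatment-failure absolute stroke volume) violates
the additivity identity that every other column satisfies; the
`flow_metrics()` constructor enforces additivity by construction and makes
no attempt to reproduce that cell, which we read as a typographical error.

## The synthetic scene generator

`scene_config()` + `render_scene()` emulate an axial C2 slice with exactly
the three signal classes the segmentation model assumes:

* an **annular CSF space** (inner radius 8 px, outer 14 px at 0.6 mm
  spacing, i.e. ~1.5 cm² — a plausible C2 subarachnoid ring) carrying a
  biphasic waveform `make_csf_waveform()`: a caudal systolic lobe
  (default peak 2.4 cm/s, 45% of the cycle) followed by a cranial
  diastolic lobe (default peak 1.5 cm/s). Samples sit at phase centers
  `(k + 1/2)/T`, so no sample lands exactly on a zero crossing and the
  directional phase-count identity is exact. No published example
  waveform exists for C2 CSF; these amplitudes were chosen once so that
  the resulting flow metrics land in the range of the published healthy
  means, and are not otherwise calibrated to patient data.
* **venous voxels** (default 10% of the non-CSF voxels in the canal box)
  carrying a raised-cosine pulse (`make_venous_waveform()`, onset 0.25
  cycle, width 0.3 cycle). The pulse is pulsatile at the cardiac period
  but nearly uncorrelated with the CSF waveform (NCC ~ -0.23 at the
  defaults), realizing the scenario PUBS exists for: pulsatile
  confounders that correlation thresholding must reject.
* **static tissue** with a spatially smooth background phase offset — a
  polynomial field in radians (default a plane, coefficients
  0.05/0.04/-0.03 over normalized coordinates, i.e. tenths of cm/s of
  spurious velocity at venc 10), emulating eddy-current baseline error.
* **acquisition noise**: i.i.d. Gaussian velocity noise (default SD
  0.2 cm/s per voxel per phase), independent across the three replicated
  acquisitions.

Ground truth (masks, bounding box, waveform, flow curve, metrics) is
computed analytically from the noise-free configuration, so every
downstream stage has an oracle.

What the generator does *not* emulate: coil sensitivity and magnitude
shading, eddy-current dynamics, gating jitter, partial-volume boundary
voxels, through-plane motion, and anatomical variation of the canal
cross-section. Passing tests therefore demonstrate correctness of the
algorithmic chain under the stated signal model, not clinical performance
on patient data.

## Canal detection

The published pipeline fine-tunes a YOLOv4 detector on annotated magnitude
images; neither the weights nor the training corpus are distributable, so
the package ships a classical default behind the same contract: per-voxel
temporal SD of decoded velocity (a pulsatility saliency map), Gaussian
smoothing (sigma 1.5 px), Otsu thresholding, tightest box around the
largest connected component, padded 2 px. Externally produced boxes
(including any trained detector's) enter through `detector = "external"`
and the CSV import in `average_precision()`'s detection schema. The
IoU >= 0.5 match criterion and ranked-detection average precision use the
all-points (continuous) interpolation — the modern convention, chosen
because the source of the published AP value does not state which variant
it used; that published value (0.91 on a private test set) is context, not
a reproducible target.

## Reference waveform and segmentation

The canal-box traces form a `V x T` matrix. After temporal centering, a
fixed-point ICA (`ica::icafast`) with `k = 3` components — CSF, blood,
static tissue being the assumed mixture — is run on the whitened data with
a seeded random orthogonal initialization; non-convergence triggers up to
3 reseeded retries, all recorded in the result. Components are scored by
*pulsatility*: the fraction of spectral power in the first two cardiac
harmonics of the gated cycle. Components below the floor (default 0.5)
are discarded, as are components with `|NCC| < 0.5` to the top-scoring
one (the published description filters "low-similarity" signals without
naming a metric or threshold; both knobs are exposed in the API). Because
ICA components are mutually decorrelated, this typically retains exactly
the dominant pulsatile component.

The preliminary reference is *not* the abstract source time course: with
only `T = 32` samples the ICA rotation carries appreciable estimation
noise. Instead, retained components are sign-aligned and averaged, and the
reference is the loading-weighted average of the voxel signals explained
by that source — a reconstruction in data space that denoises the
estimate by roughly the square root of the number of contributing voxels
(on the default scene, NCC to the true waveform improves from ~0.95 to
>0.999). It is then normalized to zero mean, unit SD, and oriented
cranial-positive against the mean trace of the 25% most pulsatile voxels.

Segmentation is single-pass: each voxel's zero-lag NCC against the
reference is thresholded at 0.5 (ties included, per the stated final
criterion; zero-variance voxels are excluded). No lag search is performed
because gated series are phase-locked. Whether the original procedure
iterated the reference from the refined mask is not stated; the module is
single-pass, and the returned NCC map makes threshold sweeps free.

## Background correction and acquisition averaging

Static-tissue phase should be zero; hardware imperfections shift it by a
spatially smooth field. The correction fits a degree-1 polynomial (by
least squares, over voxels auto-selected as the lowest 30% of temporal SD
outside the detected canal) to the temporal-mean velocity and subtracts
it from every frame. A plane is the standard PC-MRI baseline model with
minimal free parameters; the degree is configurable, and a degree-1 fit of
a quadratic field is documented model misfit, not failure. Because the
correction is constant in time it cannot alter any voxel's pulsatile
component.

Three consecutive acquisitions are combined at the *metric* level
(compute per acquisition, then average element-wise), which is robust to
small inter-acquisition misregistration; whether the original analysis
averaged images, waveforms, or metrics is not stated, so the choice is
exposed (`averaging = "waveform"` averages the flow curves instead).
Averaging cuts the random metric error by about `1/sqrt(3)` on the
generator (measured ratio ~0.67); note that for any single scalar metric
the combined estimate beats *all three* individual acquisitions in only a
minority of trials — an elementary property of averaging unbiased errors —
so the tests assert the error reduction against the typical (mean)
single-acquisition error instead.

## Cohort statistics

`mann_whitney()` uses the exact two-sided null for combined `n <= 20`
without ties, else the normal approximation with continuity and tie
corrections; `fisher_exact()` is two-sided by the point-probability
method; `normality_check()` is the Lilliefors-corrected one-sample KS
test. `roc()` computes the empirical AUC through the Mann-Whitney
identity (ties count one half), auto-orients so AUC >= 0.5 and records
the direction, and reports the cutoff maximizing the Youden index over
midpoints between adjacent observed values, smallest cutoff on ties —
deterministic and threshold-stable. The published tables report single
cutoff/sensitivity/specificity triplets without naming a selection
criterion; Youden is the field standard and reproduces that structure.
`binormal_auc()` provides the closed-form oracle
`Phi((mu_1 - mu_0)/sqrt(sd_1^2 + sd_0^2))` that pins the simulation
targets. Significance is two-sided at 0.05 throughout. Bootstrap
confidence intervals and optimism correction are out of scope (a
future-work item in the source analysis); `simulate_metric_cohort()`
truncates draws at zero because flow magnitudes are physical quantities.

## Problem sizes, numerics, degenerate inputs

* Default scene: 64 x 64 px, 32 phases, 3 acquisitions; the full test
  suite runs in under a minute on one CPU, and the acceptance script's
  replicate simulations (3 x 2000 cohorts of 31 + 26 subjects) in well
  under a minute. These sizes were chosen as the smallest at which every
  spatial stage (smoothing, Otsu, connected components, ICA) operates in
  its intended regime.
* ICA uses tolerance 1e-6, at most 200 fixed-point iterations, and
  reduces `k` to the numerical rank (singular values above `1e-8` of the
  largest); rank-1 input short-circuits to the principal temporal
  component. Structureless input (e.g. pure noise) is diagnosed as a
  degenerate-signal error — scored even when ICA fails to converge — so
  optimizer failure is only reported when a pulsatile component exists.
* Zero-variance traces: excluded from segmentation (`NA` in the NCC map),
  an error in `ncc()` itself.
* Empty directions in a flow curve yield zero for that direction's
  metrics; an empty mask is an error.
* All stochastic stages are governed by explicit seeds; identical
  configurations give bit-identical scenes, cohorts, and reports (the
  report embeds a hash of the scientific configuration).

## Known limitations

Single axial slice only (no multi-slice or 4D flow); no phase unwrapping
(aliased configurations are rejected at generation); no DICOM reader in
this implementation — cine input enters via NIfTI + JSON sidecar or the
plain-text CSV dialect, with trigger-time re-sorting supported through
sidecar metadata; the built-in detector is a classical stand-in validated
on synthetic scenes, not a trained network; clinical performance figures
from the source cohorts (patient-level means, cutoffs, near-perfect
treatment-response AUCs) cannot be reproduced without the clinical data
and are treated as context or as simulation targets pinned by the
published group parameters.
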