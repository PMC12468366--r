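Package: csfflow
Title: Automated Quantification of Spinal CSF Flow from Cine Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying pulsatile cerebrospinal fluid (CSF) flow
    at the upper cervical spine from ECG-gated cine phase-contrast MRI.
    Detects the spinal canal on magnitude images, derives a CSF reference
    velocity waveform by temporal independent component analysis, segments
    flowing CSF by pulsatility-based thresholding of normalized
    cross-correlation maps, corrects background phase, and computes directional
    flow metrics (mean, peak and per-cycle total flow, stroke volume, net
    output). Includes a synthetic cine scene generator with analytic ground
    truth, cohort simulation from published group summaries, and the
    statistical layer (Mann-Whitney, Fisher/chi-square, ROC with Youden
    cutoffs) used to separate patient groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    ica,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
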