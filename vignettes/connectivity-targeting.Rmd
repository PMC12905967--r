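---
title: "Connectivity-guided TMS targeting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-guided TMS targeting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcTarget)
```

## Overview

`fcTarget` implements a personalised transcranial magnetic stimulation
(TMS) targeting pipeline for migraine: the stimulation site in the left
dorsolateral prefrontal cortex (DLPFC) is chosen per patient as the
cluster of voxels whose resting-state BOLD signal is most strongly
correlated with a pregenual cingulate (PGC) seed time series. The
package also implements the outcome statistics of an open-label
repeated-measures trial design (baseline, post-treatment, follow-up)
and an ROC analysis of connectivity change as a treatment-response
biomarker.

Real patient scans are not shipped; every statistical and imaging
routine is exercised on seeded synthetic data generated by the package
itself, so every number in the documentation is reproducible from a
seed.

## The imaging pipeline

1. **Containers.** `VoxelGrid` stores the array shape and a 4x4
   voxel-to-mm affine; `VolumeMask`, `ScalarVolume` and `BoldSeries`
   (frames x voxels) attach data to a grid. `readVolume()` /
   `writeVolume()` handle NIfTI-1 with both sform and qform set from
   the grid affine.
2. **Regions.** The DLPFC search region is the union of four 20-mm
   spheres at MNI (−36, 39, 43), (−44, 40, 29), (−41, 16, 54) and
   (−37, 26, 49) (`buildDlpfcMask()`). Sphere membership is inclusive
   (distance ≤ radius). The PGC seed region uses a stand-in 6-mm sphere
   at (0, 40, 4) when no subject-specific map is supplied.
3. **Temporal filtering.** `highpass()` projects out a discrete cosine
   basis with `K = floor(2 * T * TR * cutoff)` functions plus the
   intercept (cutoff 0.01 Hz by default). The projection is idempotent;
   at T = 600, TR = 1 s a 0.001 Hz drift is attenuated to below 10%
   amplitude while 0.10 Hz fluctuations are preserved above 95%.
4. **Spatial smoothing.** `smoothGaussian()` applies a separable
   Gaussian (FWHM 4 mm by default) whose per-axis kernel matrix is
   column-normalised, so each frame's total intensity is conserved
   exactly, including at the volume boundary, and the impulse response
   at the half-maximum radius equals the closed-form Gaussian value.
5. **Seed series.** `seedmapSeries()` computes the sign-aware weighted
   average `sum(w_v * x_v(t)) / sum(|w_v|)` over gray matter with the
   DLPFC excluded, so anticorrelated voxels contribute with their sign
   rather than being rectified.
6. **Targeting.** `mapConnectivity()` correlates every DLPFC voxel with
   the seed series; `selectTopFraction()` keeps the top 0.5% of search
   voxels (`k = ceiling(0.005 * N)`, ties broken by larger r then lower
   voxel index); `connectedComponents()` clusters them under
   26-connectivity; `locateTarget()` reports the centroid, the snapped
   (nearest in-cluster) voxel and the peak voxel of the largest
   cluster.
7. **Connectivity change.** `deltaFC()` processes both sessions
   identically (high-pass, smooth), averages the BOLD signal in a 10-mm
   sphere at the pre-session centroid, correlates it with the seedmap
   series of each session, and reports the Fisher-z difference
   `atanh(r_post) - atanh(r_pre)`.

## The synthetic phantom

`makePhantom()` simulates a two-session resting scan on a 4-mm MNI
grid by default:

- a latent band-limited course `s(t)` is shared by the PGC region and a
  planted DLPFC "hotspot" (8-mm sphere at (−40, 32, 40)); hotspot
  voxels receive `gain * s(t)` plus unit white noise;
- the group connectivity-weight map is the smoothed indicator of the
  coupled regions, max-normalised;
- a structured confound is added: spatially smooth (8-mm FWHM),
  *temporally white* noise at amplitude 0.3.

The confound is deliberately temporally white. An earlier rank-1 design
(one shared confound time course multiplied by a smooth spatial map)
injected a coherent component into both the seed series and the search
voxels, which biased the correlation map irrespective of the planted
coupling. Real pipelines remove such global components during denoising,
which is out of scope here, so the phantom models the *residual* noise
after that step: spatially correlated but temporally unstructured. With
this generator the pipeline recovers the planted hotspot centroid
within 2 voxels in 20 of 20 seeded phantoms at the default
signal-to-noise ratio.

## The synthetic cohort

`makeCohort()` simulates n = 21 patients. Monthly headache days at
baseline follow a truncated normal (mean 10.2, SD 7.1, range 3–30,
rounded). A latent responder flag (probability 11/21) selects the
per-class proportional reduction at post-treatment and follow-up
(responders 0.55 ± 0.15, non-responders 0.10 ± 0.12, between-timepoint
jitter 0.03). Reductions are clipped to `[1 - 31/baseline, 1]` rather
than `[0, 1]`: the lower bound keeps headache days within 0–31 while
still permitting *worsening*, which is required both for the patient
global impression of change (PGIC) "worsening" category and for the
existence of a genuine null cohort (zero-mean reductions) used in the
type-I-error validation. Connectivity change is drawn per class
(non-responders centred at −0.05; responders shifted by the planted
effect), and intensity/PSQI follow integer scales with a planted
improvement.

## Outcome statistics

- `protocolTotals()`: 10 Hz x 5-s trains x 36 trains = 1800 pulses in
  about 18 minutes per session.
- `classifyResponder()`: ≥ 30% reduction in monthly headache days
  (boundary inclusive).
- `pairedBonferroni()` / `pairedBonferroniSummary()`: Dunn–Bonferroni
  paired comparisons, CI = mean ± t(1 − α/(2m), n − 1) · SD/√n, with
  paired Cohen's d = mean/SD.
- `rmAnova()`: univariate repeated-measures ANOVA across the three
  timepoints.
- `kruskalWallisEta2()`: tie-corrected H with η² = (H − k + 1)/(N − k).
- `pgicChisquare()`: goodness-of-fit of the PGIC categories against
  uniformity.
- `rocAuc()`: rank-based AUC (ties count one half) with an exact or
  Monte-Carlo permutation p-value and a Youden-J operating point.

## Validation strategy

The test suite checks every numerical routine against an independent
oracle: sphere masks against exhaustive distance enumeration, connected
components against a hand-rolled flood fill, top-fraction selection
against a full sort, AUC against all-pairs counting (and `pROC`),
smoothing against the closed-form Gaussian impulse response, and the
paired/rank statistics against their textbook formulas. Stochastic
properties (hotspot recovery, chance-level null AUC, family-wise
type-I error ≤ 0.06 under Bonferroni adjustment) are validated over
thousands of seeded simulations. The problem sizes of those simulations
(20 phantoms, 2000 cohorts, 100 masks) are the package's own validation
choices, sized to run on a single CPU in a few minutes.

## Limitations

- The e-field summary operates on a synthetic stand-in field; no
  electromagnetic modelling is performed.
- The phantom has no motion, physiological noise or registration error;
  it validates the analysis code, not acquisition robustness.
- The cohort generator is a parametric idealisation of one trial's
  summary statistics, not a patient-level dataset.
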