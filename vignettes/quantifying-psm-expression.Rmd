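---
title: "Quantifying striped PSM expression in whole-mount 3D stacks"
author: "psmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying striped PSM expression in whole-mount 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmquant)
```

## The measurement problem

Quantitative whole-mount HCR imaging of the early mouse embryo poses a
tissue-delimitation problem: segmentation-clock genes such as *Hes7* are
expressed both in the presomitic mesoderm (PSM) and in the neural ectoderm,
so raw whole-embryo intensities confound the tissue of interest with
off-target signal. The approach implemented here delimits the PSM with a
volumetric mask built from a marker channel (*Tbx6*, PSM-restricted at the
5--6 somite stage) and reports expression as an **intensity density**: the
intensity sum of the quantified channel inside the mask divided by the mask
volume, in a.u. per cubic micrometer. Densities are compared across
genotype cohorts with mean ± s.e.m. and two-tailed Student t-tests, and
summarized as percent-of-control ratios.

Around that central measure the package implements the supporting stages a
complete analysis needs:

* **Calibration** -- flat-field shading correction
  (`shadingCorrect()`, dividing by the mean-normalized dye-derived gain
  image) and per-probe baseline subtraction (`subtractBaseline()`), with the
  cutoff calibrated on a negative reference (`calibrateBaseline()`): the
  smallest cutoff under which at most a tolerated fraction (default 1e-4)
  of negative-reference voxels remain positive. "No longer detectable" is a
  qualitative criterion in the field; the exceedance-fraction tolerance is
  our operationalization of it, and the subtract-and-clamp form (rather
  than zeroing sub-cutoff voxels) preserves relative differences above
  baseline.
* **Masking** -- Gaussian smoothing at a physical "surface detail" scale of
  3 um (interpreted as the FWHM of an anisotropic-in-voxels kernel),
  absolute-intensity thresholding, and a volume-targeted automatic
  threshold search (`autoThresholdToVolume()`) that exploits the
  monotonicity of suprathreshold volume in the threshold to land the mask
  volume inside the 9.0e6--1.1e7 um^3 window used for *Tbx6* surfaces.
  When several thresholds qualify, the largest (most conservative mask) is
  returned, which minimizes off-target inclusion; connected components
  below 1000 um^3 are discarded as speckle while both bilateral PSM bands
  are kept. Manual-annotation masks interpolate polygon outlines drawn on
  alternating z-planes by blending signed-distance transforms
  (`interpolateRoiMask()`); the interpolation rule of the original
  commercial implementation is unpublished, and linear signed-distance
  blending is the standard open equivalent.
* **Spot modeling** -- punctate signal is detected as ellipsoids of fixed
  physical size, 4 um lateral diameter and 8 um axial extent
  (`detectSpots()`); the axial elongation follows the usual
  point-spread-function semantics of commercial spot models. Sum
  intensities integrate the raw channel over the ellipsoid minus a local
  background (median over a 1.0--1.5 radius shell times the ellipsoid voxel
  count). Spots are binned into the fixed half-open intensity classes
  low [1000, 6000), low-medium [6000, 11000), medium [11000, 16000),
  medium-high [16000, 21000), high [21000, Inf) a.u. (`binSpots()`), with
  ties at internal edges going to the upper bin, and linear heat values on
  a configurable scale (`assignHeatColors()`, default 7000--20000 a.u.).
  Sub-1000 a.u. spots are excluded from quintile percentages; the separate
  1500 a.u. spot-model cutoff (`filterSpots()`) is deliberately *not*
  applied before quintile analyses, whose lowest class starts at 1000.
* **Phase classification** -- the AP intensity profile inside the mask
  (`apProfile()`) is scanned for peaks; peaks with prominence at least 20%
  of the profile range, separated by at least 40 um, are full transverse
  stripes, and each stripe's mediolateral extent is measured at half height
  above the profile floor on an AP-windowed maximum-intensity projection
  (`detectStripes()`). Phase rules at the 5--6 somite stage: three full
  stripes with the posterior one midline-limited (ML fraction <= 0.4) and
  the anterior one reaching the anterior boundary (within 5% of the mask AP
  length) is phase I; two full stripes plus a low-prominence peak
  (5--20% of range) initiating in the posterior 15% at the midline is phase
  III; two full stripes with a laterally expanded posterior stripe and the
  anterior stripe away from the boundary is phase II (`classifyPhase()`).
  The numeric thresholds (0.4, 5%, 20%, 5%, 15%, 40 um) are our
  quantitative rendering of qualitative criteria; all are arguments.
* **Trough metric** -- `troughPeakMetric()` reports the minimum of the AP
  profile between the two most prominent adjacent stripes divided by their
  mean height, a [0, 1] readout of how completely transcription clears
  between oscillatory peaks (1 = no trough).
* **Cohort statistics** -- `summarizeDensities()`, `groupTTest()` (pooled
  Student form, the classical test; Welch by flag), `expressionRatio()`
  (from group means, matching the percent-of-control phrasing), and
  `runPipeline()` for manifest-driven end-to-end runs with CSV/JSON
  artifacts. Per-bin spot comparisons are left uncorrected for multiple
  testing, matching per-bin reporting practice; a correction can be applied
  downstream.

## The synthetic embryo phantom

No raw imaging data are publicly deposited for this assay, so the package
ships a generator (`generateEmbryo()`, `generateCohort()`) whose defaults
*are* the study conditions, with complete ground truth for every stage:

* **Reference domain**: a bilateral band pair (two 85 um-wide AP-running
  bands flanking a 60 um midline gap over 460 um of AP extent, joined
  across the midline in an 80 um posterior cap, 118 um thick in DV),
  uniformly expressing the reference marker at 1000 a.u. Its volume,
  9.79e6 um^3 analytically and 9.82e6 um^3 voxelized, sits inside the
  9.0e6--1.1e7 um^3 surface-volume window.
* **Stripes**: per-phase layouts of transverse stripes, each a separable
  Gaussian bump (AP FWHM 50--78 um) with a concentric mediolateral falloff,
  riding on a uniform expression floor (floor 1500, peak 2800 a.u.).
  Phase I carries three stripes with the posterior one confined to 35% of
  the mediolateral span inside the posterior cap; phase II two wider
  laterally expanded stripes; phase III two full stripes plus a
  low-amplitude (30%) initiating posterior-midline peak. Stripe widths are
  balanced so the in-mask integrated stripe mass differs by under ~2%
  between phases -- a snapshot of an oscillation that conserves total
  signal -- so cohort densities do not depend on the random phase mix.
* **Off-target signal**: a neural-plate-like slab dorsal to the PSM at
  800 a.u., entirely outside the reference domain; it is what the masking
  stage must exclude.
* **Puncta**: the nascent-transcription channel contains diffraction-scale
  Gaussian puncta (sigma 0.8 um lateral, 1.6 um axial) whose spatial rate
  follows the stripe field with its own floor fraction (0.15), and whose
  intended sum intensities follow the control quintile mixture:
  40/30/20/10/~0.5% across the five fixed bins, drawn uniformly within the
  central 70% of each bin. Emitted totals are intended values divided by a
  capture fraction of 0.80 -- the expected fraction of a punctum's emission
  recovered by the ellipsoid-sum-minus-shell-background measurement,
  computed by numerically integrating that operator over a noiseless
  punctum with uniform sub-voxel offsets (mean 0.802, s.d. 0.02). This is
  the calibration that makes intended and measured sums commensurate.
* **Genotype effects**: multiplicative target-channel factors
  control = 1.0, 0.518 (the Fig 5-style mutant), and the allelic series
  0.81 / 0.67 / 0.20 (19%, 33%, 80% reductions).
* **Noise and shading**: scaled Poisson shot noise, Gaussian read noise
  (s.d. 3 a.u.), a constant camera baseline (10 a.u.), and a radial
  multiplicative vignette falling to 0.75 at the field edge -- the standard
  confocal noise approximation. `generateFlatfield()` emits the vignette
  sampled with dye-level noise, emulating dye-solution flat-field stacks.

```{r phantom, eval = FALSE}
spec <- defaultEmbryoSpec(phase = "I", seed = 1)
emb <- generateEmbryo(spec)
emb$image
maskVolume(emb$truth@referenceMask)
```

### Grid resolution

The whole-embryo phantom uses (5, 3, 3) um voxels over a 36 x 110 x 180
grid (~0.7 M voxels). Acquisition-scale stacks use sub-micron lateral
pixels, but every quantity the density pipeline measures -- mask volumes in
um^3, stripe spacing, smoothing scales -- is defined in physical units and
is insensitive to voxel size well below the 3 um surface-detail scale, so
the coarser default keeps a full multi-genotype cohort analyzable in
seconds per sample without changing what is being tested. Where voxel size
*does* matter -- resolving 4 um spots -- the spot phantom
(`defaultSpotSpec()`) uses the acquisition-scale 0.9 x 0.9 um lateral
pixels with a 2 um z-step (axial step chosen; acquisition z-steps are
rarely reported for this assay) over a smaller field, with puncta kept two
detection radii apart and margins that keep every integration ellipsoid
inside the grid. `miniEmbryoSpec()` is a further-scaled phantom
(~4.6e5 um^3 domain, volume window `c(4.0e5, 5.2e5)`) for examples and
smoke tests only.

## What the phantoms do and do not establish

Passing the phantom benchmarks shows that the *measurement chain* is
correct and unbiased: shading correction inverts a known vignette; the
volume-targeted threshold search lands in the prescribed window on a
domain whose true volume is known; densities recover configured genotype
factors within fractions of a point; spot sums recover intended
intensities; the phase classifier recovers generating phases through
realistic noise. The phantoms do not emulate optical blur beyond spot
elongation, depth-dependent attenuation, tissue autofluorescence
gradients, per-embryo anatomical variability, or photobleaching, so
performance on real stacks depends additionally on acquisition quality in
ways these tests cannot certify. Mutant-phase classification in real data
is acknowledged to be hard even for experts; the accuracy benchmarks here
are control-condition benchmarks.

## Numerical choices and degenerate inputs

* Volume search: exact selection over the sorted smoothed intensities
  rather than a tolerance-based bisection; deterministic, and ties
  (plateau fields) are detected and reported rather than silently split.
  An unattainable window errors with the nearest achievable volumes.
* Baseline search: exact order statistic of the pooled negative-region
  values; monotone in the negative intensities by construction.
* Empty masks: `buildSurfaceMask()` warns and returns an empty mask;
  quantification of an empty mask is an error.
* Zero-variance t-tests: equal constant groups give t = 0, p = 1; unequal
  constant groups give p = 0 flagged degenerate.
* Peak finding: plateau-top peaks are assigned their center bin;
  edge-adjacent peaks get one-sided prominence, which is why the phase I
  anterior stripe is generated slightly interior to the boundary (center
  at 9% of the AP length) while still satisfying the anterior-boundary
  criterion.
* Stack I/O: integer-valued stacks round-trip exactly through 16-bit TIFF;
  non-integer data are stored as 32-bit samples with a quantization step of
  ~2e-10 of the data range. Voxel spacing travels in a JSON sidecar, and a
  stack with neither sidecar nor explicit spacing is an error, never a
  guess.

## Reproducing the benchmark numbers

`scripts/acceptance.R --seed 0 --out results/acceptance.json` regenerates
every cohort from scratch and recomputes: the Fig 5-style percent of
control (8 + 8 embryos), the three allelic-series percent reductions
(8 + 6, 10 + 7, 10 + 10), the lowest-bin spot percentage over six pooled
control spot phantoms, and the auto-threshold mask volume on the default
phantom. The testthat suite additionally checks classifier accuracy
(10 noise-free and 30 default-noise phantoms per phase), t-test type-I
calibration over 2000 simulated null cohort pairs at summary level, spot
recall/precision, and exact oracle equivalence of the density measure
against a naive voxel loop.
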