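# Synthetic-embryo specification constructors and per-phase stripe layouts.
#
# The phantom emulates a 5-6 somite stage PSM imaged in whole mount: a
# bilateral Tbx6-like reference domain (two AP-running bands joined across the
# midline in a posterior cap), a target channel carrying 2-3 transverse
# oscillatory stripes on a uniform expression floor plus off-target
# neural-plate-like signal dorsal to the PSM, and a punctate
# nascent-transcription channel whose spatial rate follows the stripes.

#' Construct a SyntheticSpec
#'
#' Low-level constructor; most users want \code{\link{defaultEmbryoSpec}} or
#' \code{\link{defaultSpotSpec}}.
#'
#' @param gridShape voxels per axis (z, y, x).
#' @param spacing um per axis (z, y, x).
#' @param psmGeometry,stripeParams,offtargetParams,punctaParams,noiseParams,vignetteParams
#'   parameter lists; see \linkS4class{SyntheticSpec} for the fields.
#' @param genotypeEffects named numeric factors in (0, 1.5].
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(gridShape, spacing, psmGeometry, stripeParams,
                          offtargetParams, punctaParams, genotypeEffects,
                          noiseParams, vignetteParams, seed = 0L) {
  new("SyntheticSpec", gridShape = as.integer(gridShape),
      spacing = .checkSpacing(spacing), psmGeometry = psmGeometry,
      stripeParams = stripeParams, offtargetParams = offtargetParams,
      punctaParams = punctaParams, genotypeEffects = genotypeEffects,
      noiseParams = noiseParams, vignetteParams = vignetteParams,
      seed = as.integer(seed))
}

.defaultGenotypeEffects <- c(control = 1.0, fgf4mut_fig5 = 0.518,
                             hes7het_fig7 = 0.81, fgf4mut_fig7 = 0.67,
                             compound_fig7 = 0.20)

.defaultBinWeights <- c(low = 0.40, low_medium = 0.30, medium = 0.20,
                        medium_high = 0.10, high = 0.005) / 1.005

#' Default whole-embryo phantom specification
#'
#' The study-condition phantom: a PSM domain of ~9.8e6 um^3 (inside the
#' 9.0e6-1.1e7 um^3 surface-volume window used for Tbx6 masks), reference
#' intensity 1000 a.u., target stripes of peak 2800 a.u. on a 1500 a.u.
#' expression floor, neural-plate off-target signal, Poisson + Gaussian
#' camera noise and a radial vignette with 25% edge falloff. Voxels are
#' (5, 3, 3) um so that a full multi-genotype cohort is analyzable in
#' seconds per sample; all tissue-scale quantities are set in physical um.
#'
#' @param phase oscillation phase of the stripe layout ("I", "II" or "III").
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- defaultEmbryoSpec(phase = "I", seed = 7)
#' emb <- generateEmbryo(spec)
#' emb$image
#' @export
defaultEmbryoSpec <- function(phase = "I", seed = 0L) {
  syntheticSpec(
    gridShape = c(36L, 110L, 180L),
    spacing = c(z = 5, y = 3, x = 3),
    psmGeometry = list(apStart = 30, apLength = 460, bandWidth = 85,
                       gapWidth = 60, capLength = 80, dvThickness = 118,
                       zCenter = 80, mlCenter = 165, refIntensity = 1000),
    stripeParams = list(peak = 2800, floor = 1500, phase = phase,
                        intronFloorFrac = 0.15),
    offtargetParams = list(intensity = 800, halfWidth = 45, thickness = 30,
                           zGap = 5),
    punctaParams = list(density = 8e-4, sigmaLateral = 0.8, sigmaAxial = 1.6,
                        minSeparationRadii = 0, captureFraction = 0.80,
                        binWeights = .defaultBinWeights, margin = 0.15),
    genotypeEffects = .defaultGenotypeEffects,
    noiseParams = list(poissonGain = 1, readSd = 3, baseline = 10),
    vignetteParams = list(minGain = 0.75, falloff = 400, center = NULL,
                          flatfieldNoiseSd = 0.005),
    seed = seed)
}

#' Default spot-phantom specification
#'
#' A fine-grid phantom for punctate-signal benchmarks: 0.9 x 0.9 um lateral
#' pixels (the paper-scale acquisition pixel size) and 2 um z-steps over a
#' ~115 x 90 x 60 um solid tissue box, with isolated diffraction-scale
#' puncta whose intended sum intensities follow the control quintile mixture
#' (40/30/20/10/~0 % across the fixed 1000-21000 a.u. bins). Puncta are kept
#' at least \code{minSeparationRadii} detection radii apart.
#'
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
defaultSpotSpec <- function(seed = 0L) {
  syntheticSpec(
    gridShape = c(40L, 128L, 128L),
    spacing = c(z = 2, y = 0.9, x = 0.9),
    psmGeometry = list(apStart = 12, apLength = 90, bandWidth = 45,
                       gapWidth = 0, capLength = 0, dvThickness = 60,
                       zCenter = 40, mlCenter = 57.6, refIntensity = 1000),
    stripeParams = list(peak = 0, floor = 0, phase = "I",
                        intronFloorFrac = 1),
    offtargetParams = list(intensity = 0, halfWidth = 0, thickness = 0,
                           zGap = 0),
    punctaParams = list(density = 3.3e-4, sigmaLateral = 0.8, sigmaAxial = 1.6,
                        minSeparationRadii = 2, captureFraction = 0.80,
                        binWeights = .defaultBinWeights, margin = 0.15),
    genotypeEffects = .defaultGenotypeEffects,
    noiseParams = list(poissonGain = 1, readSd = 3, baseline = 20),
    vignetteParams = list(minGain = 1, falloff = 200, center = NULL,
                          flatfieldNoiseSd = 0.005),
    seed = seed)
}

#' Small phantom specification for fast examples and smoke tests
#'
#' Scaled-down embryo phantom (~4.6e5 um^3 PSM) with the same anatomy and
#' noise model; pair it with a masking volume window of
#' \code{c(4.0e5, 5.2e5)} um^3.
#'
#' @param phase oscillation phase label.
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
miniEmbryoSpec <- function(phase = "I", seed = 0L) {
  spec <- defaultEmbryoSpec(phase = phase, seed = seed)
  spec@gridShape <- c(12L, 30L, 44L)
  spec@spacing <- c(z = 6, y = 5, x = 5)
  spec@psmGeometry <- list(apStart = 15, apLength = 180, bandWidth = 30,
                           gapWidth = 20, capLength = 35, dvThickness = 40,
                           zCenter = 34, mlCenter = 75, refIntensity = 1000)
  spec@offtargetParams <- list(intensity = 800, halfWidth = 18,
                               thickness = 10, zGap = 2)
  spec@punctaParams$density <- 2e-3
  spec@vignetteParams$falloff <- 150
  spec
}

#' Null-target specification for baseline calibration
#'
#' Returns a copy of \code{spec} whose target and puncta channels carry no
#' signal (stripe peak/floor, off-target intensity and puncta density all
#' zero), emulating a probe-null embryo: the target channel then contains
#' only camera baseline and noise, which is what per-probe baseline cutoffs
#' are calibrated against.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed optional seed override.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
nullTargetSpec <- function(spec, seed = spec@seed) {
  spec@stripeParams$peak <- 0
  spec@stripeParams$floor <- 0
  spec@offtargetParams$intensity <- 0
  spec@punctaParams$density <- 0
  spec@seed <- as.integer(seed)
  spec
}

# Per-phase stripe layout, in fractions of the AP length so the same anatomy
# scales from the mini to the full phantom. Widths are balanced so the
# in-mask integrated stripe mass is approximately phase-independent (a
# snapshot of a conservative oscillation); ml_fraction NA means a full
# transverse stripe spanning both bilateral bands.
.phaseStripeLayout <- function(phase) {
  switch(phase,
    I = data.frame(
      frac_center = c(0.090, 0.435, 0.900),
      frac_fwhm = c(0.130, 0.130, 0.130),
      ml_fraction = c(NA, NA, 0.35),
      amp_rel = c(1, 1, 1),
      kind = c("full", "full", "full_midline")),
    II = data.frame(
      frac_center = c(0.195, 0.585),
      frac_fwhm = c(0.170, 0.170),
      ml_fraction = c(NA, NA),
      amp_rel = c(1, 1),
      kind = c("full", "full")),
    III = data.frame(
      frac_center = c(0.130, 0.520, 0.913),
      frac_fwhm = c(0.163, 0.163, 0.108),
      ml_fraction = c(NA, NA, 0.30),
      amp_rel = c(1, 1, 0.3),
      kind = c("full", "full", "initiating")),
    stop("unknown phase '", phase, "'"))
}
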