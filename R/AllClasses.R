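#' @import methods
NULL

#' VoxelGrid: one channel's 3D intensity stack
#'
#' Container for a single-channel 3D fluorescence stack in arbitrary units,
#' together with its physical voxel spacing and the anatomical assignment of
#' the array axes. Arrays are indexed \code{(z, y, x)}; by convention the
#' anterior-posterior (AP) axis is \code{x} with anterior at \code{x = 0},
#' the mediolateral (ML) axis is \code{y}, and the dorsoventral (DV) axis is
#' \code{z}.
#'
#' @slot data 3D numeric array of non-negative intensities (a.u.).
#' @slot spacing named numeric vector \code{c(z=, y=, x=)}, um per voxel.
#' @slot channel probe/fluorophore name.
#' @slot axisMap anatomical axis assignment, default
#'   \code{c(z = "dv", y = "ml", x = "ap")}.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  slots = c(data = "array", spacing = "numeric", channel = "character",
            axisMap = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("'data' must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0) ||
        any(!is.finite(object@spacing)))
      return("'spacing' must be three strictly positive values")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      return("'data' must be finite")
    if (any(object@data < 0)) return("'data' must be non-negative")
    if (length(object@channel) != 1L) return("'channel' must be a single name")
    TRUE
  }
)

#' Construct a VoxelGrid
#'
#' @param data 3D numeric array, indexed (z, y, x).
#' @param spacing voxel spacing in um, \code{c(z, y, x)}.
#' @param channel channel name.
#' @param axisMap anatomical axis labels for (z, y, x).
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(array(1, c(4, 8, 8)), spacing = c(2, 1, 1), channel = "tbx6")
#' voxelVolume(g)
#' @export
VoxelGrid <- function(data, spacing, channel = "unnamed",
                      axisMap = c(z = "dv", y = "ml", x = "ap")) {
  new("VoxelGrid", data = data, spacing = .checkSpacing(spacing),
      channel = channel, axisMap = axisMap)
}

#' Mask3D: boolean volumetric mask
#'
#' A logical 3D array with voxel spacing; its physical volume is always the
#' true-voxel count times the voxel volume.
#'
#' @slot data logical 3D array.
#' @slot spacing named numeric vector (um per axis).
#' @slot provenance list describing how the mask was built
#'   (\code{auto_threshold}, \code{fixed_threshold} or
#'   \code{roi_interpolation}, plus parameters).
#' @exportClass Mask3D
setClass("Mask3D",
  slots = c(data = "array", spacing = "numeric", provenance = "list"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      return("'data' must be a logical 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("'spacing' must be three strictly positive values")
    TRUE
  }
)

#' Construct a Mask3D
#' @param data logical 3D array (z, y, x).
#' @param spacing voxel spacing in um.
#' @param provenance list recording how the mask was made.
#' @return A \linkS4class{Mask3D}.
#' @export
Mask3D <- function(data, spacing, provenance = list(method = "fixed_threshold")) {
  new("Mask3D", data = data, spacing = .checkSpacing(spacing),
      provenance = provenance)
}

#' BaselineCutoff: per-probe baseline calibration result
#'
#' @slot channel probe/fluorophore name.
#' @slot cutoff intensity cutoff (a.u.).
#' @slot calibrationSource \code{"negative_tissue_region"} or
#'   \code{"null_embryo"}.
#' @slot tolerance maximal fraction of above-cutoff voxels allowed in the
#'   negative reference.
#' @exportClass BaselineCutoff
setClass("BaselineCutoff",
  slots = c(channel = "character", cutoff = "numeric",
            calibrationSource = "character", tolerance = "numeric"),
  validity = function(object) {
    if (object@cutoff < 0) return("'cutoff' must be >= 0")
    if (object@tolerance < 0 || object@tolerance >= 1)
      return("'tolerance' must lie in [0, 1)")
    TRUE
  }
)

#' SpotSet: detected puncta
#'
#' Spot table with physical positions, background-subtracted sum intensities,
#' intensity-bin labels and linear heat-map values.
#'
#' @slot spots data.frame with columns \code{z_um, y_um, x_um, sum_intensity,
#'   bin_label, heat_value}.
#' @slot params list of detection parameters actually used.
#' @slot channel source channel name.
#' @exportClass SpotSet
setClass("SpotSet",
  slots = c(spots = "data.frame", params = "list", channel = "character"))

#' StripeSet: detected transverse expression stripes
#'
#' @slot stripes data.frame, one row per stripe ordered anterior to
#'   posterior: \code{ap_center_um, ap_width_um, height, prominence,
#'   ml_extent_fraction, is_full, reaches_anterior_boundary,
#'   posterior_midline_limited, initiating_at_posterior_midline}.
#' @slot profile data.frame AP profile used (\code{ap_mid_um, mean, n}).
#' @slot apRange numeric(2), AP extent of the mask in um.
#' @slot params detection parameters used.
#' @exportClass StripeSet
setClass("StripeSet",
  slots = c(stripes = "data.frame", profile = "data.frame",
            apRange = "numeric", params = "list"))

#' PhaseCall: oscillation-phase classification
#'
#' @slot phase one of \code{"I"}, \code{"II"}, \code{"III"},
#'   \code{"unclassifiable"}.
#' @slot stripeCount number of full stripes.
#' @slot criteriaTrace named logical list of every predicate tested.
#' @exportClass PhaseCall
setClass("PhaseCall",
  slots = c(phase = "character", stripeCount = "integer",
            criteriaTrace = "list"))

#' SyntheticSpec: parameters of the synthetic embryo phantom generator
#'
#' Full description of one phantom: grid geometry, the bilateral PSM band
#' domain, per-phase stripe layout, off-target (neural-plate-like) expression,
#' punctate nascent-transcription signal, genotype intensity scaling, the
#' confocal noise model and the multiplicative vignetting field.
#'
#' @slot gridShape integer voxels per axis (z, y, x).
#' @slot spacing um per axis (z, y, x).
#' @slot psmGeometry list: \code{apStart, apLength, bandWidth, gapWidth,
#'   capLength, dvThickness, zCenter, mlCenter, refIntensity} (um / a.u.).
#' @slot stripeParams list: \code{peak, floor} (a.u.), \code{phase}
#'   (\code{"I"|"II"|"III"}), \code{mlSigmaFull} (um), \code{intronFloorFrac}.
#' @slot offtargetParams list: \code{intensity, halfWidth, thickness, zGap}.
#' @slot punctaParams list: \code{density} (per um^3), \code{sigmaLateral,
#'   sigmaAxial} (um), \code{minSeparationRadii, emissionScale, binWeights,
#'   binTargets, margin}.
#' @slot genotypeEffects named numeric, multiplicative target-channel factors
#'   in (0, 1.5]; 1.0 is control.
#' @slot noiseParams list: \code{poissonGain} (0 disables), \code{readSd},
#'   \code{baseline} (a.u.).
#' @slot vignetteParams list: \code{minGain, falloff} (um), \code{center}
#'   (um, y/x; NULL = grid center), \code{flatfieldNoiseSd}.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  slots = c(gridShape = "integer", spacing = "numeric", psmGeometry = "list",
            stripeParams = "list", offtargetParams = "list",
            punctaParams = "list", genotypeEffects = "numeric",
            noiseParams = "list", vignetteParams = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      return("'gridShape' must be three positive integers")
    if (any(object@genotypeEffects <= 0) || any(object@genotypeEffects > 1.5))
      return("genotype effects must lie in (0, 1.5]")
    sp <- object@stripeParams
    if (any(c(sp$peak, sp$floor) < 0))
      return("stripe intensities must be >= 0")
    if (!sp$phase %in% c("I", "II", "III"))
      return("stripe phase must be one of I, II, III")
    if (object@offtargetParams$intensity < 0)
      return("off-target intensity must be >= 0")
    v <- object@vignetteParams
    if (v$minGain <= 0 || v$minGain > 1)
      return("vignette minGain must lie in (0, 1]")
    TRUE
  }
)

#' EmbryoImage: a multi-channel phantom or acquisition
#'
#' @slot channels named list of \linkS4class{VoxelGrid} objects; the
#'   generator emits \code{reference}, \code{target} and
#'   \code{intron_puncta}.
#' @slot sampleId sample identifier.
#' @slot genotype genotype label.
#' @slot phase oscillation phase the sample was generated in (or \code{NA}).
#' @exportClass EmbryoImage
setClass("EmbryoImage",
  slots = c(channels = "list", sampleId = "character", genotype = "character",
            phase = "character"))

#' GroundTruth: the generator's noiseless truth for one phantom
#'
#' @slot referenceMask true PSM-domain \linkS4class{Mask3D}.
#' @slot channels named list of noiseless, unvignetted intensity arrays.
#' @slot stripes data.frame of true stripes (\code{ap_center_um, ap_fwhm_um,
#'   ml_fraction, amplitude, kind}).
#' @slot phase true phase label.
#' @slot puncta data.frame of true puncta (\code{z_um, y_um, x_um,
#'   intended_sum, emitted_total}).
#' @slot genotypeFactor applied multiplicative factor.
#' @slot genotype genotype label.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(referenceMask = "Mask3D", channels = "list", stripes = "data.frame",
            phase = "character", puncta = "data.frame",
            genotypeFactor = "numeric", genotype = "character"))
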