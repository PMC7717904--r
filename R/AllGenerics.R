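#' @rdname VoxelGrid
#' @param x an object.
#' @export
setGeneric("intensityData", function(x) standardGeneric("intensityData"))

#' @rdname VoxelGrid
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VoxelGrid
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname VoxelGrid
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname Mask3D
#' @param x an object.
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' Physical volume of a mask in cubic micrometers
#' @param x a \linkS4class{Mask3D}.
#' @return volume in um^3 (true-voxel count times voxel volume).
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname SpotSet
#' @param x an object.
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname SpotSet
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname StripeSet
#' @param x an object.
#' @export
setGeneric("stripeTable", function(x) standardGeneric("stripeTable"))

#' @rdname PhaseCall
#' @param x an object.
#' @export
setGeneric("phaseLabel", function(x) standardGeneric("phaseLabel"))

#' @rdname EmbryoImage
#' @param x an object.
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname VoxelGrid
#' @export
setMethod("intensityData", "VoxelGrid", function(x) x@data)

#' @rdname VoxelGrid
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname Mask3D
#' @export
setMethod("voxelSpacing", "Mask3D", function(x) x@spacing)

#' @rdname VoxelGrid
#' @export
setMethod("channelName", "VoxelGrid", function(x) x@channel)

#' @rdname VoxelGrid
#' @export
setMethod("voxelVolume", "VoxelGrid", function(x) prod(x@spacing))

#' @rdname Mask3D
#' @export
setMethod("voxelVolume", "Mask3D", function(x) prod(x@spacing))

#' @rdname Mask3D
#' @export
setMethod("maskData", "Mask3D", function(x) x@data)

#' @rdname maskVolume
#' @export
setMethod("maskVolume", "Mask3D", function(x) sum(x@data) * prod(x@spacing))

#' @rdname SpotSet
#' @export
setMethod("spotTable", "SpotSet", function(x) x@spots)

#' @rdname SpotSet
#' @export
setMethod("nSpots", "SpotSet", function(x) nrow(x@spots))

#' @rdname StripeSet
#' @export
setMethod("stripeTable", "StripeSet", function(x) x@stripes)

#' @rdname PhaseCall
#' @export
setMethod("phaseLabel", "PhaseCall", function(x) x@phase)

#' @rdname EmbryoImage
#' @export
setMethod("getChannel", "EmbryoImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel '", name, "' in this image (available: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat("VoxelGrid '", object@channel, "': ", d[1], " x ", d[2], " x ", d[3],
      " voxels (z,y,x), spacing ", paste(signif(object@spacing, 3),
      collapse = "/"), " um, range [", signif(min(object@data), 4), ", ",
      signif(max(object@data), 4), "] a.u.\n", sep = "")
})

setMethod("show", "Mask3D", function(object) {
  cat("Mask3D: ", sum(object@data), " voxels, volume ",
      signif(maskVolume(object), 6), " um^3 (",
      object@provenance$method %||% "unknown", ")\n", sep = "")
})

setMethod("show", "SpotSet", function(object) {
  cat("SpotSet '", object@channel, "': ", nrow(object@spots), " spots",
      sep = "")
  bl <- object@spots$bin_label
  if (any(!is.na(bl))) cat(" (", sum(!is.na(bl) & bl != "unbinned"),
                           " binned)", sep = "")
  cat("\n")
})

setMethod("show", "StripeSet", function(object) {
  st <- object@stripes
  cat("StripeSet: ", nrow(st), " stripes (", sum(st$is_full), " full)\n",
      sep = "")
  if (nrow(st)) print(st[, c("ap_center_um", "ml_extent_fraction", "is_full")])
})

setMethod("show", "PhaseCall", function(object) {
  cat("PhaseCall: phase ", object@phase, " (", object@stripeCount,
      " full stripes)\n", sep = "")
})

setMethod("show", "EmbryoImage", function(object) {
  cat("EmbryoImage '", object@sampleId, "' [", object@genotype, ", phase ",
      object@phase, "]: channels ", paste(names(object@channels),
      collapse = ", "), "\n", sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: grid ", paste(object@gridShape, collapse = "x"),
      " voxels @ ", paste(object@spacing, collapse = "/"), " um, phase ",
      object@stripeParams$phase, ", seed ", object@seed, "\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
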