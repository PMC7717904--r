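# Flat-field shading correction and per-probe baseline calibration.

#' Flat-field shading correction
#'
#' Divides each xy-plane of \code{grid} by the flat field and rescales by the
#' flat field's mean, so a spatially uniform sample keeps its mean intensity:
#' \code{out = in * mean(ff) / ff}. A 3D flat-field stack is first median-
#' projected over z (the "median flat field image" of dye-solution
#' acquisitions).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param flatfield a \linkS4class{VoxelGrid} (3D dye stack) or 2D matrix
#'   with the same xy shape as \code{grid}; must be strictly positive.
#' @return The corrected \linkS4class{VoxelGrid} (spacing and channel
#'   preserved).
#' @export
shadingCorrect <- function(grid, flatfield) {
  stopifnot(is(grid, "VoxelGrid"))
  ff <- if (is(flatfield, "VoxelGrid")) flatfield@data else flatfield
  if (length(dim(ff)) == 3L) {
    ff <- apply(ff, c(2, 3), stats::median)
  }
  d <- dim(grid@data)
  if (!identical(dim(ff), d[2:3])) {
    stop("flat field xy shape ", paste(dim(ff), collapse = "x"),
         " does not match grid xy shape ", paste(d[2:3], collapse = "x"))
  }
  if (any(ff <= 0)) stop("flat field must be strictly positive everywhere")
  corr <- mean(ff) / ff
  out <- grid@data * .broadcastYX(corr, d[1])
  VoxelGrid(out, grid@spacing, channel = grid@channel, axisMap = grid@axisMap)
}

#' Calibrate a per-probe baseline cutoff from negative references
#'
#' Operationalizes "the baseline cutoff was adjusted until signal from a
#' tissue known not to express the gene was no longer detectable": returns
#' the minimal cutoff \code{c} such that the fraction of voxels with value
#' \code{> c} inside the negative reference, pooled over all supplied grids,
#' is at most \code{tolerance}. With \code{negativeRegion = NULL} the whole
#' stacks are used (probe-null embryo calibration). The search is exact over
#' the sorted negative-region values.
#'
#' @param grids a \linkS4class{VoxelGrid} or list of them.
#' @param negativeRegion optional \linkS4class{Mask3D} delimiting the
#'   negative tissue; \code{NULL} uses every voxel.
#' @param tolerance maximal allowed exceedance fraction, in [0, 1);
#'   default \code{1e-4}.
#' @param channel channel name recorded in the result (defaults to the first
#'   grid's channel).
#' @return A \linkS4class{BaselineCutoff}.
#' @export
calibrateBaseline <- function(grids, negativeRegion = NULL, tolerance = 1e-4,
                              channel = NULL) {
  if (is(grids, "VoxelGrid")) grids <- list(grids)
  stopifnot(length(grids) >= 1L, all(vapply(grids, is, TRUE, "VoxelGrid")))
  if (tolerance < 0 || tolerance >= 1) stop("'tolerance' must lie in [0, 1)")
  vals <- unlist(lapply(grids, function(g) {
    if (is.null(negativeRegion)) as.vector(g@data)
    else {
      if (!identical(dim(negativeRegion@data), dim(g@data)))
        stop("negative region shape does not match grid shape")
      g@data[negativeRegion@data]
    }
  }))
  if (!length(vals)) stop("negative reference region is empty")
  n <- length(vals)
  allowed <- floor(tolerance * n)
  sorted <- sort(vals, decreasing = TRUE)
  cutoff <- sorted[allowed + 1L]  # minimal c with #(v > c) <= allowed
  new("BaselineCutoff", channel = channel %||% grids[[1]]@channel,
      cutoff = cutoff,
      calibrationSource = if (is.null(negativeRegion)) "null_embryo"
                          else "negative_tissue_region",
      tolerance = tolerance)
}

#' Baseline subtraction
#'
#' Subtract-and-clamp: \code{out = max(in - cutoff, 0)} elementwise, which
#' removes the per-probe baseline while preserving relative differences
#' above it.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param cutoff a \linkS4class{BaselineCutoff} or a single non-negative
#'   number (a.u.).
#' @return The subtracted \linkS4class{VoxelGrid}.
#' @export
subtractBaseline <- function(grid, cutoff) {
  stopifnot(is(grid, "VoxelGrid"))
  c0 <- if (is(cutoff, "BaselineCutoff")) cutoff@cutoff else cutoff
  if (!is.numeric(c0) || length(c0) != 1L || c0 < 0) {
    stop("'cutoff' must be a single non-negative intensity")
  }
  VoxelGrid(pmax(grid@data - c0, 0), grid@spacing, channel = grid@channel,
            axisMap = grid@axisMap)
}

#' Persist / restore a baseline cutoff as JSON
#' @param cutoff a \linkS4class{BaselineCutoff}.
#' @param path JSON file path.
#' @return \code{writeBaselineCutoff}: \code{path} invisibly;
#'   \code{readBaselineCutoff}: a \linkS4class{BaselineCutoff}.
#' @export
writeBaselineCutoff <- function(cutoff, path) {
  jsonlite::write_json(list(channel = cutoff@channel, cutoff = cutoff@cutoff,
                            calibration_source = cutoff@calibrationSource,
                            tolerance = cutoff@tolerance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBaselineCutoff
#' @export
readBaselineCutoff <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BaselineCutoff", channel = m$channel, cutoff = m$cutoff,
      calibrationSource = m$calibration_source, tolerance = m$tolerance)
}
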