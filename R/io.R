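# Stack I/O. Stacks are written as multi-page TIFF (one page per z-plane)
# holding data divided by a recorded scale, with a JSON sidecar (<path>.json)
# carrying the scale, voxel spacing and channel name. Integer-valued data up
# to 65535 (i.e. ordinary microscopy counts) take a 16-bit path that
# round-trips exactly; anything else is stored as 32-bit samples with a
# quantization step of scale/(2^32 - 1), i.e. ~2e-10 of the data range.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a VoxelGrid to a TIFF stack
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param path destination TIFF path; a JSON metadata sidecar is written
#'   next to it.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readStack}}
#' @export
writeStack <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  a <- grid@data
  mx <- max(a, 1e-12)
  if (all(a == round(a)) && mx <= 65535) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- 2^ceiling(log2(mx))
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                   reduce = FALSE))
  jsonlite::write_json(list(scale = scale, bits = bits,
                            spacing_um = as.list(grid@spacing),
                            channel = grid@channel,
                            axis_map = as.list(grid@axisMap),
                            shape_zyx = dim(a)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF stack into one or more VoxelGrids
#'
#' Reads a multi-page TIFF written by \code{\link{writeStack}} (using its
#' JSON sidecar for scale/spacing/channel) or any plain multi-page TIFF, in
#' which case \code{spacing} must be supplied explicitly and values are used
#' as stored. A file holding \code{nChannels} interleaved channels is split
#' into that many grids.
#'
#' @param path TIFF path.
#' @param spacing optional explicit voxel spacing (z, y, x) in um; required
#'   when no sidecar is present.
#' @param channel optional channel name override.
#' @param nChannels number of interleaved channels in the file.
#' @return A \linkS4class{VoxelGrid}, or a named list of them when
#'   \code{nChannels > 1}.
#' @export
readStack <- function(path, spacing = NULL, channel = NULL, nChannels = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  integerData <- FALSE
  axisMap <- c(z = "dv", y = "ml", x = "ap")
  meta <- NULL
  if (file.exists(.sidecarPath(path))) {
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    scale <- meta$scale
    integerData <- identical(meta$bits, 16L) || identical(meta$bits, 16)
    if (is.null(spacing)) spacing <- unlist(meta$spacing_um)
    if (is.null(channel)) channel <- meta$channel
    if (!is.null(meta$axis_map)) axisMap <- unlist(meta$axis_map)
  }
  if (is.null(spacing)) {
    stop("stack '", path, "' carries no voxel-spacing metadata; ",
         "supply 'spacing' explicitly")
  }
  nz <- length(pages) %/% nChannels
  if (nz * nChannels != length(pages)) {
    stop("page count ", length(pages), " is not a multiple of nChannels")
  }
  build <- function(idx, nm) {
    a <- array(0, c(length(idx), dim(pages[[1]])[1], dim(pages[[1]])[2]))
    for (k in seq_along(idx)) {
      p <- pages[[idx[k]]]
      if (length(dim(p)) == 3L) p <- p[, , 1]
      a[k, , ] <- p
    }
    a <- a * scale
    if (integerData) a <- round(a)  # undo 16-bit de-quantization exactly
    VoxelGrid(a, spacing, channel = nm, axisMap = axisMap)
  }
  if (nChannels == 1L) {
    build(seq_len(nz), channel %||% "unnamed")
  } else {
    nms <- if (!is.null(channel) && length(channel) == nChannels) channel
           else paste0("channel", seq_len(nChannels))
    out <- lapply(seq_len(nChannels), function(c)
      build(seq(c, length(pages), by = nChannels), nms[c]))
    names(out) <- nms
    out
  }
}
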