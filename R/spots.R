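# Spot modeling: detection of punctate signal as fixed-size ellipsoids
# (4 um lateral diameter, 8 um axial extent by default), local-background-
# subtracted sum intensities, the fixed five-bin intensity scheme and linear
# heat-map colors.

#' Spot detection parameters
#'
#' @param diameter lateral spot diameter in um (default 4).
#' @param psfAxial axial spot extent in um (default 8); must be >= diameter.
#'   The point-spread elongation makes spots ellipsoids of lateral radius
#'   \code{diameter/2} and axial radius \code{psfAxial/2}.
#' @param localBackground subtract the median of a surrounding shell
#'   (1.0-1.5 spot radii) times the ellipsoid voxel count (default TRUE).
#' @param minSumIntensity default sum-intensity threshold for
#'   \code{\link{filterSpots}} (default 1500).
#' @param noiseK local maxima must exceed the smoothed-image background by
#'   \code{noiseK} robust standard deviations (default 8).
#' @return list of class \code{SpotDetectParams}.
#' @export
spotDetectParams <- function(diameter = 4, psfAxial = 8, localBackground = TRUE,
                             minSumIntensity = 1500, noiseK = 8) {
  stopifnot(diameter > 0, psfAxial >= diameter)
  structure(list(diameter = diameter, psfAxial = psfAxial,
                 localBackground = localBackground,
                 minSumIntensity = minSumIntensity, noiseK = noiseK),
            class = "SpotDetectParams")
}

#' The fixed five-bin spot intensity scheme
#'
#' Half-open sum-intensity bins (a.u.): low [1000, 6000), low-medium
#' [6000, 11000), medium [11000, 16000), medium-high [16000, 21000),
#' high [21000, Inf). Spots below 1000 are left unbinned.
#'
#' @param edges strictly increasing bin boundaries.
#' @param labels one label per interval (top interval unbounded).
#' @return list of class \code{SpotBinningScheme}.
#' @export
spotBinningScheme <- function(edges = c(1000, 6000, 11000, 16000, 21000),
                              labels = c("low", "low_medium", "medium",
                                         "medium_high", "high")) {
  stopifnot(all(diff(edges) > 0), length(labels) == length(edges))
  structure(list(edges = edges, labels = labels), class = "SpotBinningScheme")
}

# Sum of raw intensities over the ellipsoid around one center, and the local
# background estimate from a surrounding shell.
.spotSum <- function(a, co, ctr, rLat, rAx, localBackground) {
  d <- dim(a)
  rz <- rAx; ry <- rLat; rx <- rLat
  zi <- which(abs(co[[1]] - ctr[1]) <= 1.5 * rz)
  yi <- which(abs(co[[2]] - ctr[2]) <= 1.5 * ry)
  xi <- which(abs(co[[3]] - ctr[3]) <= 1.5 * rx)
  sub <- a[zi, yi, xi, drop = FALSE]
  u2 <- outer(((co[[1]][zi] - ctr[1]) / rz)^2,
              outer(((co[[2]][yi] - ctr[2]) / ry)^2,
                    ((co[[3]][xi] - ctr[3]) / rx)^2, `+`), `+`)
  inEll <- u2 <= 1
  s <- sum(sub[inEll])
  nVox <- sum(inEll)
  if (localBackground) {
    shell <- u2 > 1 & u2 <= 1.5^2
    bg <- if (any(shell)) stats::median(sub[shell]) else 0
    s <- s - bg * nVox
  }
  max(s, 0)
}

#' Detect spots in a channel
#'
#' Matched-filter blob detection: the channel is smoothed with an
#' anisotropic Gaussian at the spot scale (sigma = diameter/4 laterally,
#' psfAxial/4 axially), strict 3D local maxima above
#' \code{background + noiseK * mad} are taken as candidate centers,
#' duplicates closer than one (anisotropic) spot radius are merged keeping
#' the brighter, and each spot's sum intensity integrates the raw channel
#' over its ellipsoid minus, when enabled, the median of a 1.0-1.5 radius
#' shell times the ellipsoid voxel count.
#'
#' @param channel a \linkS4class{VoxelGrid}.
#' @param params a \code{\link{spotDetectParams}}.
#' @param mask optional \linkS4class{Mask3D}; only spots whose centers fall
#'   inside it are returned.
#' @return A \linkS4class{SpotSet}.
#' @export
detectSpots <- function(channel, params = spotDetectParams(), mask = NULL) {
  stopifnot(is(channel, "VoxelGrid"))
  sp <- channel@spacing
  rLat <- params$diameter / 2
  rAx <- params$psfAxial / 2
  if (sp[1] > rAx || sp[2] > rLat || sp[3] > rLat) {
    warning("voxel spacing is coarser than the spot radius along some axis; ",
            "detection is sub-resolution")
  }
  a <- channel@data
  sm <- .gaussianSmooth3D(a, c(rAx / 2, rLat / 2, rLat / 2), sp)
  bg <- stats::median(sm)
  noise <- stats::mad(sm)
  thr <- bg + params$noiseK * max(noise, 1e-9)
  pk <- .localMaxima3D(sm, thr)
  emptySet <- function() new("SpotSet",
    spots = data.frame(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                       sum_intensity = numeric(), bin_label = character(),
                       heat_value = numeric(), stringsAsFactors = FALSE),
    params = unclass(params), channel = channel@channel)
  if (nrow(pk) == 0L) return(emptySet())
  co <- .axisCoords2(dim(a), sp)
  ctrs <- cbind(co[[1]][pk[, 1]], co[[2]][pk[, 2]], co[[3]][pk[, 3]])
  vals <- sm[pk]
  # merge maxima closer than one radius (anisotropic metric), brightest first
  o <- order(vals, decreasing = TRUE)
  keep <- integer()
  scl <- c(rAx, rLat, rLat)
  for (i in o) {
    if (length(keep)) {
      u <- sweep(ctrs[keep, , drop = FALSE], 2, ctrs[i, ])
      if (min(rowSums(sweep(u, 2, scl, `/`)^2)) < 1) next
    }
    keep <- c(keep, i)
  }
  pk <- pk[keep, , drop = FALSE]
  ctrs <- ctrs[keep, , drop = FALSE]
  if (!is.null(mask)) {
    inMask <- mask@data[pk]
    pk <- pk[inMask, , drop = FALSE]
    ctrs <- ctrs[inMask, , drop = FALSE]
  }
  if (nrow(pk) == 0L) return(emptySet())
  sums <- vapply(seq_len(nrow(pk)), function(i)
    .spotSum(a, co, ctrs[i, ], rLat, rAx, params$localBackground), numeric(1))
  new("SpotSet",
      spots = data.frame(z_um = ctrs[, 1], y_um = ctrs[, 2], x_um = ctrs[, 3],
                         sum_intensity = sums, bin_label = NA_character_,
                         heat_value = NA_real_, stringsAsFactors = FALSE),
      params = unclass(params), channel = channel@channel)
}

.axisCoords2 <- function(d, sp) lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * sp[ax])

#' Filter spots by sum intensity
#'
#' Retains spots with \code{sum_intensity >= minSumIntensity} (boundary
#' inclusive); the default 1500 a.u. is the cutoff used for spot models.
#'
#' @param spots a \linkS4class{SpotSet}.
#' @param minSumIntensity threshold (a.u.).
#' @return The filtered \linkS4class{SpotSet}.
#' @export
filterSpots <- function(spots, minSumIntensity = spots@params$minSumIntensity) {
  spots@spots <- spots@spots[spots@spots$sum_intensity >= minSumIntensity, ,
                             drop = FALSE]
  rownames(spots@spots) <- NULL
  spots
}

#' Bin spots into the fixed intensity scheme
#'
#' Each spot is labeled by the half-open interval \code{[lo, hi)} containing
#' its sum intensity; the top interval is unbounded ("21,000 or greater")
#' and spots below the first edge are labeled \code{"unbinned"}.
#'
#' @param spots a \linkS4class{SpotSet}.
#' @param scheme a \code{\link{spotBinningScheme}}.
#' @return The labeled \linkS4class{SpotSet}.
#' @export
binSpots <- function(spots, scheme = spotBinningScheme()) {
  s <- spots@spots$sum_intensity
  idx <- findInterval(s, scheme$edges)  # 0 = below first edge
  spots@spots$bin_label <- c("unbinned", scheme$labels)[idx + 1L]
  spots
}

#' Fraction of binned spots per intensity label
#'
#' @param spots a binned \linkS4class{SpotSet} (or a list of them, pooled).
#' @param scheme the \code{\link{spotBinningScheme}} used (for label order).
#' @return named numeric vector of percentages over binned spots
#'   (sums to 100).
#' @export
quintileDistribution <- function(spots, scheme = spotBinningScheme()) {
  if (is(spots, "SpotSet")) spots <- list(spots)
  labs <- unlist(lapply(spots, function(s) s@spots$bin_label))
  if (anyNA(labs)) stop("spots must be binned (binSpots) first")
  labs <- labs[labs != "unbinned"]
  if (!length(labs)) stop("no binned spots")
  tab <- table(factor(labs, levels = scheme$labels))
  100 * as.vector(tab) / length(labs) -> pct
  names(pct) <- scheme$labels
  pct
}

#' Assign linear heat-map colors
#'
#' \code{heat_value = clamp((sum_intensity - min) / (max - min), 0, 1)}, the
#' linear color scale used for intensity heat maps (e.g. 7000-20000 a.u.).
#'
#' @param spots a \linkS4class{SpotSet}.
#' @param scale numeric(2), \code{c(min, max)} in a.u. with min < max.
#' @return The \linkS4class{SpotSet} with \code{heat_value} populated.
#' @export
assignHeatColors <- function(spots, scale = c(7000, 20000)) {
  stopifnot(length(scale) == 2L, scale[1] < scale[2])
  h <- (spots@spots$sum_intensity - scale[1]) / (scale[2] - scale[1])
  spots@spots$heat_value <- pmin(pmax(h, 0), 1)
  spots
}

#' Write a spot table to CSV
#' @param spots a \linkS4class{SpotSet}.
#' @param path CSV destination.
#' @return \code{path}, invisibly.
#' @export
writeSpots <- function(spots, path) {
  utils::write.csv(spots@spots, path, row.names = FALSE)
  invisible(path)
}
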