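# Manual-annotation masking: closed 2D polygons on sparse z-planes,
# rasterized exactly and interpolated to intervening planes by blending
# signed-distance transforms (the in-silico analogue of drawing the mesoderm
# outline "on alternating z-planes" and interpolating).

# Even-odd scanline rasterization of a closed polygon given voxel-center
# coordinates; py/px in um, matching the (y, x) axes.
.rasterPolygon <- function(py, px, yc, xc) {
  ny <- length(yc); nx <- length(xc)
  inside <- matrix(FALSE, ny, nx)
  n <- length(py)
  j <- n
  for (i in seq_len(n)) {
    yi <- py[i]; yj <- py[j]; xi <- px[i]; xj <- px[j]
    straddle <- (yi > yc) != (yj > yc)
    rows <- which(straddle)
    for (r in rows) {
      xint <- xi + (yc[r] - yi) / (yj - yi) * (xj - xi)
      flip <- xc < xint
      inside[r, flip] <- !inside[r, flip]
    }
    j <- i
  }
  inside
}

# Do two closed segments properly intersect (excluding shared endpoints)?
.segIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.checkSimplePolygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  seg <- function(i) list(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      a <- seg(i); b <- seg(j)
      if (.segIntersect(a[[1]], a[[2]], b[[1]], b[[2]])) {
        stop("polygon is self-intersecting")
      }
    }
  }
  invisible(TRUE)
}

# Signed Euclidean distance (pixels) of a binary plane: positive inside.
.signedDistance <- function(m) {
  img <- EBImage::Image(m * 1)
  dIn <- EBImage::distmap(img)
  dOut <- EBImage::distmap(EBImage::Image(1 - m))
  as.matrix(dIn) - as.matrix(dOut)
}

#' Interpolate a 3D mask from polygon annotations on sparse z-planes
#'
#' Annotated planes are rasterized exactly (even-odd rule at voxel centers);
#' each intervening plane is filled by linearly blending the signed-distance
#' transforms of the two bounding annotated planes and thresholding at zero;
#' planes outside the annotated range copy the nearest annotated plane.
#'
#' @param annotations list of \code{list(z = <plane index>, poly = <n x 2
#'   matrix of (y_um, x_um) vertices>)}; at least two planes, simple
#'   (non-self-intersecting) polygons.
#' @param gridShape mask shape (z, y, x) in voxels.
#' @param spacing voxel spacing (z, y, x) in um; y and x spacing should be
#'   equal (isotropic in-plane pixels), as the in-plane distance transform
#'   is computed in pixels.
#' @return A \linkS4class{Mask3D} with \code{roi_interpolation} provenance.
#' @export
interpolateRoiMask <- function(annotations, gridShape, spacing) {
  spacing <- .checkSpacing(spacing)
  if (length(annotations) < 2L) {
    stop("at least two annotated planes are required for interpolation")
  }
  if (abs(spacing[2] - spacing[3]) > 1e-9) {
    warning("anisotropic in-plane spacing; signed distances assume square pixels")
  }
  gridShape <- as.integer(gridShape)
  zs <- vapply(annotations, function(a) as.integer(a$z), integer(1))
  if (anyDuplicated(zs)) stop("duplicate annotated plane indices")
  o <- order(zs)
  zs <- zs[o]; annotations <- annotations[o]
  if (zs[1] < 1L || zs[length(zs)] > gridShape[1]) {
    stop("annotated plane index outside the z-stack")
  }
  yc <- (seq_len(gridShape[2]) - 0.5) * spacing[2]
  xc <- (seq_len(gridShape[3]) - 0.5) * spacing[3]
  rasters <- lapply(annotations, function(a) {
    poly <- as.matrix(a$poly)
    .checkSimplePolygon(poly)
    .rasterPolygon(poly[, 1], poly[, 2], yc, xc)
  })
  sdist <- lapply(rasters, .signedDistance)
  m <- array(FALSE, gridShape)
  for (z in seq_len(gridShape[1])) {
    if (z <= zs[1]) {
      plane <- rasters[[1]]
    } else if (z >= zs[length(zs)]) {
      plane <- rasters[[length(zs)]]
    } else if (z %in% zs) {
      plane <- rasters[[match(z, zs)]]
    } else {
      i <- findInterval(z, zs)
      w <- (z - zs[i]) / (zs[i + 1L] - zs[i])
      plane <- ((1 - w) * sdist[[i]] + w * sdist[[i + 1L]]) >= 0
    }
    m[z, , ] <- plane
  }
  Mask3D(m, spacing,
         provenance = list(method = "roi_interpolation",
                           annotated_planes = zs))
}
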