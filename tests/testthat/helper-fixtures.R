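# Shared fixtures, all generated in code.

# A small random integer-valued grid (microscopy-count-like).
randomGrid <- function(dim = c(6L, 8L, 10L), spacing = c(2, 1, 1),
                       maxVal = 5000L, seed = 1L, channel = "test") {
  set.seed(seed)
  a <- array(as.numeric(sample.int(maxVal, prod(dim), replace = TRUE)), dim)
  VoxelGrid(a, spacing, channel = channel)
}

# A random logical mask with a guaranteed non-empty interior.
randomMask <- function(dim = c(6L, 8L, 10L), spacing = c(2, 1, 1),
                       p = 0.4, seed = 2L) {
  set.seed(seed)
  m <- array(runif(prod(dim)) < p, dim)
  m[3, 4, 5] <- TRUE
  Mask3D(m, spacing)
}

# A grid whose intensity depends on x only: f evaluated at voxel centers.
profileGrid <- function(f, nx = 60L, ny = 6L, nz = 4L, spacing = c(2, 2, 2),
                        channel = "profile") {
  x <- (seq_len(nx) - 0.5) * spacing[3]
  a <- aperm(array(rep(f(x), each = nz * ny), c(nz, ny, nx)), c(1, 2, 3))
  VoxelGrid(a, spacing, channel = channel)
}

fullMask <- function(grid) {
  Mask3D(array(TRUE, dim(intensityData(grid))), voxelSpacing(grid))
}

# Mini-phantom masking config matching miniEmbryoSpec().
miniMaskConfig <- function() {
  maskingConfig(volumeWindow = c(4.0e5, 5.2e5))
}

# Deposit n Gaussian puncta of given totals at given um positions onto a
# baseline grid; independent implementation of blob deposition (loops over
# every voxel of each blob's bounding box).
punctaGrid <- function(pos, totals, dim = c(30L, 64L, 64L),
                       spacing = c(2, 0.9, 0.9), sig = c(1.6, 0.8, 0.8),
                       baseline = 20, noiseSd = 2, seed = 5L) {
  set.seed(seed)
  a <- array(0, dim)
  co <- lapply(1:3, function(ax) (seq_len(dim[ax]) - 0.5) * spacing[ax])
  for (k in seq_len(nrow(pos))) {
    w <- outer(exp(-(co[[1]] - pos[k, 1])^2 / (2 * sig[1]^2)),
               outer(exp(-(co[[2]] - pos[k, 2])^2 / (2 * sig[2]^2)),
                     exp(-(co[[3]] - pos[k, 3])^2 / (2 * sig[3]^2))))
    a <- a + totals[k] * w / sum(w)
  }
  a <- a + baseline + array(rnorm(prod(dim), 0, noiseSd), dim)
  VoxelGrid(pmax(a, 0), spacing, channel = "puncta")
}

# Greedy matching of detected spots to true positions within an anisotropic
# tolerance; returns counts for recall/precision.
matchSpots <- function(spotDf, truthDf, tolLat = 1.5, tolAx = 3) {
  used <- rep(FALSE, nrow(spotDf))
  hits <- 0L
  for (i in seq_len(nrow(truthDf))) {
    d2 <- ((spotDf$z_um - truthDf$z_um[i]) / tolAx)^2 +
          ((spotDf$y_um - truthDf$y_um[i]) / tolLat)^2 +
          ((spotDf$x_um - truthDf$x_um[i]) / tolLat)^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && d2[j] <= 1) {
      hits <- hits + 1L
      used[j] <- TRUE
    }
  }
  list(hits = hits, nTrue = nrow(truthDf), nDet = nrow(spotDf))
}
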