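# Surface masking, volume-targeted thresholding, ROI interpolation and
# masked intensity density.

test_that("fixed-threshold masks behave at the extremes and recover a box volume", {
  cfg <- maskingConfig(smoothingScale = 0.1, volumeWindow = c(1, 2),
                       minComponentVolume = 0)
  g <- randomGrid(c(6L, 8L, 8L), spacing = c(1, 1, 1), seed = 3L)
  m0 <- buildSurfaceMask(g, cfg, threshold = 0)
  expect_identical(sum(maskData(m0)), as.integer(prod(dim(intensityData(g)))))
  expect_warning(mB <- buildSurfaceMask(g, cfg, threshold = 1e9), "empty")
  expect_identical(maskVolume(mB), 0)
  # binary box of known volume, negligible smoothing
  a <- array(0, c(10, 12, 14))
  a[3:8, 4:9, 5:10] <- 100
  box <- VoxelGrid(a, c(2, 2, 2), "box")
  vTrue <- 6 * 6 * 6 * 8
  for (thr in c(1, 50, 100)) {
    expect_equal(maskVolume(buildSurfaceMask(box, cfg, thr)), vTrue)
  }
})

test_that("mask volume is non-increasing in the threshold on random smooth fields", {
  cfg <- maskingConfig(smoothingScale = 4, volumeWindow = c(1, 2),
                       minComponentVolume = 0)
  for (seed in 1:4) {
    g <- randomGrid(c(8L, 10L, 10L), spacing = c(2, 2, 2), seed = seed)
    thrs <- seq(500, 4500, by = 500)
    vols <- vapply(thrs, function(t)
      maskVolume(suppressWarnings(buildSurfaceMask(g, cfg, t))), numeric(1))
    expect_true(all(diff(vols) <= 0))
  }
})

test_that("component filtering removes speckle but keeps bilateral bodies", {
  a <- array(0, c(6, 20, 20))
  a[2:5, 2:8, 2:18] <- 100    # band 1: 952 um^3 at 2 um voxels -> 5712
  a[2:5, 12:18, 2:18] <- 100  # band 2
  a[3, 10, 10] <- 100         # single-voxel speckle (8 um^3)
  g <- VoxelGrid(a, c(2, 2, 2), "ref")
  cfg <- maskingConfig(smoothingScale = 0.1, volumeWindow = c(1, 2),
                       minComponentVolume = 100)
  m <- buildSurfaceMask(g, cfg, threshold = 50)
  expect_false(maskData(m)[3, 10, 10])
  expect_true(all(maskData(m)[2:5, 2:8, 2:18]))
  expect_true(all(maskData(m)[2:5, 12:18, 2:18]))
})

test_that("auto threshold matches an exhaustive scan oracle on a radial field", {
  # smooth nested-spheres field: suprathreshold volume known by brute force
  d <- c(12L, 24L, 24L)
  co <- lapply(1:3, function(ax) seq_len(d[ax]) - (d[ax] + 1) / 2)
  r2 <- outer(co[[1]]^2, outer(co[[2]]^2, co[[3]]^2, `+`), `+`)
  a <- 1000 * exp(-r2 / 60)
  g <- VoxelGrid(a, c(1, 1, 1), "radial")
  cfg <- maskingConfig(smoothingScale = 1e-3, volumeWindow = c(200, 260),
                       minComponentVolume = 0)
  res <- autoThresholdToVolume(g, cfg)
  vol <- maskVolume(res$mask)
  expect_gte(vol, 200)
  expect_lte(vol, 260)
  # brute-force scan over every distinct value: the largest threshold whose
  # volume is in the window
  vals <- sort(unique(as.vector(a)), decreasing = TRUE)
  volsAll <- vapply(vals, function(t) sum(a >= t), numeric(1))
  ok <- which(volsAll >= 200 & volsAll <= 260)
  expect_equal(res$threshold, vals[ok[1]], tolerance = 1e-9)
  expect_identical(vol, volsAll[ok[1]])
  # determinism
  res2 <- autoThresholdToVolume(g, cfg)
  expect_identical(res2$threshold, res$threshold)
})

test_that("auto threshold handles plateaus, single-voxel windows and unattainable windows", {
  # plateau: binary field, any threshold in (0, max] gives the same volume
  a <- array(0, c(6, 10, 10))
  a[2:5, 3:8, 3:8] <- 100
  g <- VoxelGrid(a, c(5, 5, 5), "bin")  # 144 voxels * 125 = 18000
  cfg <- maskingConfig(smoothingScale = 1e-3, volumeWindow = c(17000, 19000),
                       minComponentVolume = 0)
  res <- autoThresholdToVolume(g, cfg)
  expect_identical(maskVolume(res$mask), 144 * 125)
  # integer-distinct smooth field, window of exactly one voxel
  b <- array(as.numeric(1:60), c(3, 4, 5))
  gb <- VoxelGrid(b, c(1, 1, 1), "b")
  cfgb <- maskingConfig(smoothingScale = 1e-3, volumeWindow = c(0.5, 1.5),
                        minComponentVolume = 0)
  resb <- autoThresholdToVolume(gb, cfgb)
  expect_identical(maskVolume(resb$mask), 1)
  expect_equal(resb$threshold, 60, tolerance = 1e-9)
  # unattainable: a plateau jumps straight over a narrow window
  cfgU <- maskingConfig(smoothingScale = 1e-3, volumeWindow = c(100, 200),
                        minComponentVolume = 0)
  expect_error(autoThresholdToVolume(g, cfgU), "unattainable")
})

test_that("masked density equals a naive voxel loop and is linear in the grid", {
  naiveDensity <- function(grid, mask) {
    a <- intensityData(grid); m <- maskData(mask)
    s <- 0; n <- 0L
    d <- dim(a)
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (m[z, y, x]) { s <- s + a[z, y, x]; n <- n + 1L }
    }
    s / (n * prod(voxelSpacing(grid)))
  }
  g <- randomGrid(c(5L, 6L, 7L), spacing = c(2, 1.5, 1.5), seed = 20L)
  m <- randomMask(c(5L, 6L, 7L), spacing = c(2, 1.5, 1.5), seed = 21L)
  meas <- maskedIntensityDensity(g, m)
  expect_identical(meas$density, naiveDensity(g, m))
  expect_equal(meas$density * meas$volume_um3, meas$intensity_sum,
               tolerance = 1e-12)
  # zeroing the grid outside the mask leaves the result unchanged
  a0 <- intensityData(g); a0[!maskData(m)] <- 0
  expect_identical(maskedIntensityDensity(VoxelGrid(a0, voxelSpacing(g)), m)$density,
                   meas$density)
  # linearity: density(aX + bY) = a density(X) + b density(Y)
  g2 <- randomGrid(c(5L, 6L, 7L), spacing = c(2, 1.5, 1.5), seed = 22L)
  comb <- VoxelGrid(2 * intensityData(g) + 3 * intensityData(g2),
                    voxelSpacing(g))
  expect_equal(maskedIntensityDensity(comb, m)$density,
               2 * meas$density + 3 * maskedIntensityDensity(g2, m)$density,
               tolerance = 1e-12)
})

test_that("masked density validates shapes, emptiness and the uniform-field case", {
  u <- VoxelGrid(array(5, c(5, 5, 8)), c(1, 1, 1), "u")
  m <- Mask3D(array(FALSE, c(5, 5, 8)), c(1, 1, 1))
  md <- maskData(m); md[2:3, 2:5, 1:5] <- TRUE  # 200 voxels? 2*4*5*... adjust
  m@data <- md
  nIn <- sum(md)
  meas <- maskedIntensityDensity(u, m)
  expect_equal(meas$intensity_sum, 5 * nIn)
  expect_equal(meas$density, 5)
  z <- VoxelGrid(array(0, c(5, 5, 8)), c(1, 1, 1))
  expect_equal(maskedIntensityDensity(z, m)$density, 0)
  expect_error(maskedIntensityDensity(u, Mask3D(array(FALSE, c(5, 5, 8)),
                                                c(1, 1, 1))), "empty")
  expect_error(maskedIntensityDensity(u, Mask3D(array(TRUE, c(5, 5, 7)),
                                                c(1, 1, 1))), "shape")
})

test_that("ROI interpolation reproduces annotated planes and blends distances between them", {
  sq <- function(half, c0 = 32) rbind(c(c0 - half, c0 - half),
                                      c(c0 - half, c0 + half),
                                      c(c0 + half, c0 + half),
                                      c(c0 + half, c0 - half))
  # identical squares on planes 1 and 3 -> plane 2 is the same square
  m <- interpolateRoiMask(list(list(z = 1, poly = sq(10)),
                               list(z = 3, poly = sq(10))),
                          c(3L, 64L, 64L), c(2, 1, 1))
  expect_identical(maskData(m)[2, , ], maskData(m)[1, , ])
  expect_identical(maskVolume(m), sum(maskData(m)) * 2)
  # concentric circles r=10 and r=20 -> midplane radius 15 +/- 1 voxel
  th <- seq(0, 2 * pi, length.out = 91)[-91]
  circ <- function(r) cbind(32 + r * sin(th), 32 + r * cos(th))
  mc <- interpolateRoiMask(list(list(z = 1, poly = circ(10)),
                                list(z = 3, poly = circ(20))),
                           c(5L, 64L, 64L), c(2, 1, 1))
  rMid <- sqrt(sum(maskData(mc)[2, , ]) / pi)
  expect_lt(abs(rMid - 15), 1)
  # planes outside the annotated range copy the nearest annotated plane
  expect_identical(maskData(mc)[4, , ], maskData(mc)[3, , ])
  expect_identical(maskData(mc)[5, , ], maskData(mc)[3, , ])
  # a single annotated plane is not interpolatable
  expect_error(interpolateRoiMask(list(list(z = 1, poly = sq(5))),
                                  c(3L, 64L, 64L), c(2, 1, 1)),
               "two annotated planes")
  # self-intersecting polygons are rejected
  bow <- rbind(c(10, 10), c(20, 20), c(10, 20), c(20, 10))
  expect_error(interpolateRoiMask(list(list(z = 1, poly = bow),
                                       list(z = 3, poly = sq(5))),
                                  c(3L, 64L, 64L), c(2, 1, 1)),
               "self-intersecting")
})
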