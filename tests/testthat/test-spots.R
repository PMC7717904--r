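# Spot detection, intensity filtering, fixed binning, quintile counting and
# heat colors.

test_that("an all-zero channel yields an empty SpotSet", {
  z <- VoxelGrid(array(0, c(10, 20, 20)), c(2, 0.9, 0.9), "p")
  expect_identical(nSpots(detectSpots(z)), 0L)
})

test_that("isolated puncta are recovered at their positions with faithful sums", {
  set.seed(9)
  pos <- cbind(z = runif(10, 15, 45), y = runif(10, 10, 47),
               x = runif(10, 10, 47))
  # enforce generous pairwise separation
  while (min(dist(sweep(pos, 2, c(4, 2, 2), `/`))) < 2.5) {
    pos <- cbind(runif(10, 15, 45), runif(10, 10, 47), runif(10, 10, 47))
  }
  totals <- seq(4000, 22000, length.out = 10)
  g <- punctaGrid(pos, totals)
  ss <- detectSpots(g)
  st <- spotTable(ss)
  expect_identical(nrow(st), 10L)
  mt <- matchSpots(st, data.frame(z_um = pos[, 1], y_um = pos[, 2],
                                  x_um = pos[, 3]),
                   tolLat = 0.9, tolAx = 2)  # within one voxel
  expect_identical(mt$hits, 10L)
  # local background subtraction cancels a uniform offset (< 2% change)
  gOff <- VoxelGrid(intensityData(g) + 50, voxelSpacing(g), "p")
  stOff <- spotTable(detectSpots(gOff))
  expect_identical(nrow(stOff), 10L)
  o1 <- order(st$x_um); o2 <- order(stOff$x_um)
  rel <- abs(stOff$sum_intensity[o2] - st$sum_intensity[o1]) /
    st$sum_intensity[o1]
  expect_lt(max(rel), 0.02)
})

test_that("close maxima are merged keeping the brighter spot", {
  pos <- rbind(c(30, 25, 25), c(30, 25, 27))  # 2 um apart laterally (< 1 radius)
  g <- punctaGrid(pos, c(20000, 8000), noiseSd = 0.5)
  expect_identical(nrow(spotTable(detectSpots(g))), 1L)
})

test_that("sub-resolution spacing triggers a warning", {
  g <- randomGrid(c(4L, 8L, 8L), spacing = c(5, 3, 3), seed = 2L)
  expect_warning(detectSpots(g), "sub-resolution")
})

test_that("intensity filtering is inclusive at the boundary", {
  ss <- new("SpotSet",
            spots = data.frame(z_um = 1:3, y_um = 1:3, x_um = 1:3,
                               sum_intensity = c(1000, 1500, 2000),
                               bin_label = NA_character_,
                               heat_value = NA_real_),
            params = list(), channel = "p")
  expect_identical(nSpots(filterSpots(ss, 1500)), 2L)
  expect_identical(nSpots(filterSpots(ss, 0)), 3L)
  expect_identical(nSpots(filterSpots(ss, Inf)), 0L)
})

test_that("binning follows the half-open fixed scheme with an unbounded top bin", {
  mk <- function(s) new("SpotSet",
                        spots = data.frame(z_um = 0, y_um = 0, x_um = 0,
                                           sum_intensity = s,
                                           bin_label = NA_character_,
                                           heat_value = NA_real_),
                        params = list(), channel = "p")
  lab <- function(s) spotTable(binSpots(mk(s)))$bin_label
  expect_identical(lab(5000), "low")
  expect_identical(lab(12000), "medium")
  expect_identical(lab(22000), "high")
  expect_identical(lab(6000), "low_medium")   # ties go to the upper bin
  expect_identical(lab(21000), "high")
  expect_identical(lab(500), "unbinned")
  expect_identical(lab(999.99), "unbinned")
  expect_identical(lab(1000), "low")
})

test_that("quintile fractions count binned spots, sum to 100 and match a hand tally", {
  set.seed(30)
  s <- c(runif(40, 1000, 6000), runif(10, 6000, 11000), runif(3, 21000, 30000),
         runif(5, 0, 1000))
  ss <- binSpots(new("SpotSet",
                     spots = data.frame(z_um = seq_along(s), y_um = 0, x_um = 0,
                                        sum_intensity = s,
                                        bin_label = NA_character_,
                                        heat_value = NA_real_),
                     params = list(), channel = "p"))
  q <- quintileDistribution(ss)
  expect_equal(sum(q), 100, tolerance = 1e-9)
  expect_equal(unname(q), 100 * c(40, 10, 0, 0, 3) / 53)
  # invariant to spot ordering
  ss2 <- ss; ss2@spots <- ss2@spots[rev(seq_len(nrow(ss2@spots))), ]
  expect_equal(quintileDistribution(ss2), q)
  # 4 low + 1 high
  s5 <- binSpots(new("SpotSet",
                     spots = data.frame(z_um = 1:5, y_um = 0, x_um = 0,
                                        sum_intensity = c(2000, 3000, 4000,
                                                          5000, 25000),
                                        bin_label = NA_character_,
                                        heat_value = NA_real_),
                     params = list(), channel = "p"))
  expect_equal(unname(quintileDistribution(s5)), c(80, 0, 0, 0, 20))
  # all unbinned errors
  s0 <- binSpots(new("SpotSet",
                     spots = data.frame(z_um = 1, y_um = 0, x_um = 0,
                                        sum_intensity = 10,
                                        bin_label = NA_character_,
                                        heat_value = NA_real_),
                     params = list(), channel = "p"))
  expect_error(quintileDistribution(s0), "no binned spots")
})

test_that("filtering at a bin edge commutes with binning", {
  set.seed(31)
  s <- runif(200, 0, 25000)
  mk <- function(v) new("SpotSet",
                        spots = data.frame(z_um = seq_along(v), y_um = 0,
                                           x_um = 0, sum_intensity = v,
                                           bin_label = NA_character_,
                                           heat_value = NA_real_),
                        params = list(), channel = "p")
  a <- binSpots(filterSpots(mk(s), 6000))
  b <- filterSpots(binSpots(mk(s)), 6000)
  expect_equal(spotTable(a)$bin_label, spotTable(b)$bin_label)
})

test_that("heat colors are the clamped linear scale of the figure legends", {
  ss <- new("SpotSet",
            spots = data.frame(z_um = 1:5, y_um = 0, x_um = 0,
                               sum_intensity = c(7000, 20000, 13500, 1000,
                                                 30000),
                               bin_label = NA_character_,
                               heat_value = NA_real_),
            params = list(), channel = "p")
  h <- spotTable(assignHeatColors(ss, c(7000, 20000)))$heat_value
  expect_equal(h, c(0, 1, 0.5, 0, 1))
})
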