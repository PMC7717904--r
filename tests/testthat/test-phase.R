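# AP profiles, stripe detection, phase classification and the trough metric.

test_that("AP profiles are exact bin means and conserve the masked sum", {
  u <- VoxelGrid(array(7, c(4, 6, 40)), c(2, 2, 2), "u")
  m <- fullMask(u)
  p <- apProfile(u, m, binWidth = 8)
  expect_true(all(p$mean == 7))
  expect_equal(sum(p$mean * p$n), maskedIntensityDensity(u, m)$intensity_sum)
  # a pure f(x) field reproduces f at the bin centers
  f <- function(x) 100 + 50 * sin(x / 30)
  g <- profileGrid(f, nx = 90L, spacing = c(2, 2, 2))
  pf <- apProfile(g, fullMask(g), binWidth = 2)  # one voxel per bin
  expect_equal(pf$mean, f(pf$ap_mid_um), tolerance = 1e-12)
  expect_equal(sum(pf$sum), sum(intensityData(g)))
  expect_error(apProfile(u, Mask3D(array(FALSE, c(4, 6, 40)), c(2, 2, 2))),
               "empty")
})

test_that("stripe detection finds no stripes in constant fields and merges close peaks", {
  u <- VoxelGrid(array(5, c(4, 6, 60)), c(2, 2, 2), "u")
  expect_identical(nrow(stripeTable(detectStripes(u, fullMask(u)))), 0L)
  # two Gaussian bumps 24 um apart with a 40 um separation floor merge to one
  f2 <- function(x) 100 + 900 * (exp(-(x - 58)^2 / 50) + exp(-(x - 82)^2 / 50))
  g2 <- profileGrid(f2, nx = 70L, spacing = c(2, 2, 2))
  st2 <- stripeTable(detectStripes(g2, fullMask(g2), minSeparation = 40))
  expect_identical(sum(st2$is_full), 1L)
  # well-separated bumps survive
  f3 <- function(x) 100 + 900 * (exp(-(x - 40)^2 / 200) + exp(-(x - 110)^2 / 200))
  g3 <- profileGrid(f3, nx = 75L, spacing = c(2, 2, 2))
  expect_identical(sum(stripeTable(detectStripes(g3, fullMask(g3)))$is_full), 2L)
})

test_that("stripe detection recovers generated stripe positions within one bin", {
  for (ph in c("I", "II", "III")) {
    e <- generateEmbryo(defaultEmbryoSpec(phase = ph, seed = 60L))
    ss <- detectStripes(getChannel(e$image, "target"), e$truth@referenceMask)
    st <- stripeTable(ss)
    truth <- e$truth@stripes
    expect_identical(nrow(st), nrow(truth))
    expect_true(all(abs(st$ap_center_um - truth$ap_center_um) <= 9))
    expect_true(all(diff(st$ap_center_um) > 0))
    expect_true(all(st$ml_extent_fraction >= 0 & st$ml_extent_fraction <= 1))
  }
})

test_that("the classification rules fire in the documented order", {
  mkStripes <- function(df) {
    new("StripeSet", stripes = df,
        profile = data.frame(ap_mid_um = 0, mean = 0, sum = 0, n = 1,
                             smoothed = 0),
        apRange = c(0, 100), params = list(fMid = 0.4))
  }
  base <- data.frame(ap_center_um = c(10, 50, 90), ap_width_um = 20,
                     height = 1, prominence = 1,
                     ml_extent_fraction = c(0.7, 0.7, 0.35),
                     is_full = TRUE,
                     reaches_anterior_boundary = c(TRUE, FALSE, FALSE),
                     posterior_midline_limited = c(FALSE, FALSE, TRUE),
                     initiating_at_posterior_midline = FALSE)
  expect_identical(phaseLabel(classifyPhase(mkStripes(base))), "I")
  # two full + posterior initiating -> III
  s3 <- base
  s3$is_full[3] <- FALSE
  s3$posterior_midline_limited[3] <- FALSE
  s3$initiating_at_posterior_midline[3] <- TRUE
  expect_identical(phaseLabel(classifyPhase(mkStripes(s3))), "III")
  # two full, posterior expanded, anterior away from the boundary -> II
  s2 <- base[2:3, ]
  s2$ml_extent_fraction <- c(0.7, 0.8)
  s2$posterior_midline_limited <- FALSE
  expect_identical(phaseLabel(classifyPhase(mkStripes(s2))), "II")
  # no stripes -> unclassifiable, and the trace records the tested predicates
  pc0 <- classifyPhase(mkStripes(base[0, ]))
  expect_identical(phaseLabel(pc0), "unclassifiable")
  expect_identical(pc0@criteriaTrace$n_full_stripes, 0L)
  expect_named(pc0@criteriaTrace,
               c("n_full_stripes", "posterior_midline_limited",
                 "anterior_reaches_boundary", "posterior_laterally_expanded",
                 "initiating_at_posterior_midline"))
})

test_that("the trough ratio is the between-peak minimum over the mean peak height", {
  # piecewise-linear profile with peaks 10 and 6 and trough 2 -> 2/8 = 0.25;
  # vertices placed at bin centers so the sampled profile is exact
  f <- function(x) {
    v <- ifelse(x <= 41, 10 * x / 41,
         ifelse(x <= 81, 10 - 8 * (x - 41) / 40,
         ifelse(x <= 121, 2 + 4 * (x - 81) / 40, 6 - 6 * (x - 121) / 59)))
    pmax(v, 0)
  }
  g <- profileGrid(f, nx = 90L, spacing = c(2, 2, 2))
  r <- troughPeakMetric(g, fullMask(g), profileSmoothBins = 0, binWidth = 2)
  expect_equal(r, 0.25, tolerance = 1e-9)
  # raised cosine: trough 0 between peaks of 1 -> ratio 0
  f0 <- function(x) pmax(0.5 - 0.5 * cos((x - 10) * pi / 40), 0) *
    (x >= 10 & x <= 170)
  g0 <- profileGrid(f0, nx = 95L, spacing = c(2, 2, 2))
  r0 <- troughPeakMetric(g0, fullMask(g0), profileSmoothBins = 0, binWidth = 2)
  expect_lt(r0, 0.02)
  # fewer than two stripes errors
  g1 <- profileGrid(function(x) 100 + 900 * exp(-(x - 60)^2 / 200), nx = 60L)
  expect_error(troughPeakMetric(g1, fullMask(g1)), "fewer than 2")
})

test_that("the intron trough is shallower when transcription fails to clear", {
  ctl <- c(); mut <- c()
  for (s in 1:3) {
    spc <- defaultEmbryoSpec(phase = "II", seed = 200L + s)
    ec <- generateEmbryo(spc)
    ctl <- c(ctl, troughPeakMetric(getChannel(ec$image, "intron_puncta"),
                                   ec$truth@referenceMask))
    spm <- spc
    spm@stripeParams$intronFloorFrac <- 0.5  # blurred-trough condition
    spm@seed <- 300L + s
    em <- generateEmbryo(spm, genotype = "fgf4mut_fig5")
    mut <- c(mut, troughPeakMetric(getChannel(em$image, "intron_puncta"),
                                   em$truth@referenceMask))
  }
  expect_gt(mean(mut), mean(ctl))
  expect_true(all(ctl >= 0 & ctl <= 1, mut >= 0 & mut <= 1))
})

test_that("a uniformly phased cohort classifies close to one third per label", {
  coh <- generateCohort(defaultEmbryoSpec(), c(control = 30L), baseSeed = 77L)
  calls <- vapply(coh$samples, function(s) {
    ss <- detectStripes(getChannel(s$image, "target"),
                        s$truth@referenceMask)
    phaseLabel(classifyPhase(ss))
  }, character(1))
  freq <- table(factor(calls, levels = c("I", "II", "III"))) / 30
  expect_true(all(abs(freq - 1 / 3) <= 0.15))
})
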