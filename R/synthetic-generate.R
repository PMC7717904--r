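# Phantom generation: noiseless structural fields, puncta placement, the
# vignette/noise forward model, flat fields and cohorts.

# Voxel-center coordinates in um along each axis.
.axisCoords <- function(spec) {
  lapply(1:3, function(ax) (seq_len(spec@gridShape[ax]) - 0.5) * spec@spacing[ax])
}

# Broadcast an (ny, nx) matrix over z into a (nz, ny, nx) array.
.broadcastYX <- function(m, nz) {
  aperm(array(m, c(dim(m), nz)), c(3L, 1L, 2L))
}

# Logical (nz, ny, nx) indicator of the bilateral PSM band domain: two
# AP-running bands flanking a midline gap, joined across the midline in the
# posterior cap, of uniform DV thickness.
.psmDomain <- function(spec) {
  g <- spec@psmGeometry
  co <- .axisCoords(spec)
  dz <- abs(co[[1]] - g$zCenter)
  dy <- abs(co[[2]] - g$mlCenter)
  x <- co[[3]]
  inZ <- dz <= g$dvThickness / 2
  inAP <- x >= g$apStart & x <= g$apStart + g$apLength
  halfW <- g$gapWidth / 2 + g$bandWidth
  band <- dy >= g$gapWidth / 2 & dy <= halfW
  central <- dy <= halfW
  inCap <- inAP & x >= g$apStart + g$apLength - g$capLength
  yx <- outer(band, inAP, `&`) | outer(central, inCap, `&`)
  outer(inZ, yx, `&`)
}

# Analytic volume of the domain in um^3 (used by spec-level checks).
#' True PSM-domain volume implied by a spec's geometry
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return volume in um^3 computed from the analytic geometry.
#' @export
psmDomainVolume <- function(spec) {
  g <- spec@psmGeometry
  (2 * g$bandWidth * g$apLength + g$gapWidth * g$capLength) * g$dvThickness
}

# True stripe table in absolute um for a spec.
.stripeTruth <- function(spec) {
  g <- spec@psmGeometry
  lay <- .phaseStripeLayout(spec@stripeParams$phase)
  fullSpan <- g$gapWidth + 2 * g$bandWidth
  data.frame(
    ap_center_um = g$apStart + lay$frac_center * g$apLength,
    ap_fwhm_um = lay$frac_fwhm * g$apLength,
    ml_fraction = ifelse(is.na(lay$ml_fraction), 1, lay$ml_fraction),
    ml_sigma_um = ifelse(is.na(lay$ml_fraction), 0.52 * fullSpan,
                         lay$ml_fraction * fullSpan / 2.355),
    amplitude = lay$amp_rel * (spec@stripeParams$peak - spec@stripeParams$floor),
    amp_rel = lay$amp_rel,
    kind = lay$kind)
}

# Normalized (ny, nx) stripe modulation in [0, ~1]: sum of separable
# Gaussian bumps (AP profile x concentric ML falloff), the generator's
# rendering of "a concentric gradient of signal intensity with highest
# expression at the center" of each stripe.
.stripeModulation <- function(spec, truth = .stripeTruth(spec)) {
  co <- .axisCoords(spec)
  y <- co[[2]]; x <- co[[3]]
  g <- spec@psmGeometry
  m <- matrix(0, length(y), length(x))
  for (i in seq_len(nrow(truth))) {
    sx <- truth$ap_fwhm_um[i] / 2.355
    bx <- exp(-(x - truth$ap_center_um[i])^2 / (2 * sx^2))
    gy <- exp(-(y - g$mlCenter)^2 / (2 * truth$ml_sigma_um[i]^2))
    m <- m + truth$amp_rel[i] * outer(gy, bx)
  }
  m
}

# Off-target (neural-plate-like) slab dorsal to the PSM, outside the domain.
.offtargetField <- function(spec) {
  ot <- spec@offtargetParams
  if (ot$intensity <= 0) return(array(0, spec@gridShape))
  g <- spec@psmGeometry
  co <- .axisCoords(spec)
  zTop <- g$zCenter + g$dvThickness / 2
  inZ <- co[[1]] > zTop + ot$zGap & co[[1]] <= zTop + ot$zGap + ot$thickness
  inY <- abs(co[[2]] - g$mlCenter) <= ot$halfWidth
  inX <- co[[3]] >= g$apStart & co[[3]] <= g$apStart + g$apLength
  ot$intensity * outer(inZ, outer(inY, inX))
}

# 2D (ny, nx) multiplicative vignette gain in [minGain, 1].
.vignetteGain2D <- function(spec) {
  v <- spec@vignetteParams
  co <- .axisCoords(spec)
  ctr <- v$center
  if (is.null(ctr)) {
    ctr <- c(y = max(co[[2]]) / 2, x = max(co[[3]]) / 2)
  }
  d2 <- outer((co[[2]] - ctr[1])^2, (co[[3]] - ctr[2])^2, `+`)
  v$minGain + (1 - v$minGain) * exp(-d2 / (2 * v$falloff^2))
}

# Draw intended spot sum intensities from the quintile mixture: uniform
# within the central (1 - 2*margin) of each fixed bin; the open top bin uses
# [22000, 28000].
.drawIntendedSums <- function(n, pp) {
  edges <- c(1000, 6000, 11000, 16000, 21000)
  lo <- c(edges[1:4], 22000)
  hi <- c(edges[2:5], 28000)
  m <- pp$margin
  lo2 <- lo + m * (hi - lo)
  hi2 <- hi - m * (hi - lo)
  bin <- sample.int(5L, n, replace = TRUE, prob = pp$binWeights)
  runif(n, lo2[bin], hi2[bin])
}

# Place puncta and deposit them into a field. Returns list(field, puncta df).
# With minSeparationRadii > 0 positions are uniform in the domain with an
# anisotropic hard-core exclusion (in units of the 2 um lateral / 4 um axial
# detection radii); otherwise positions are voxel-sampled proportional to
# `rate` and jittered within the voxel.
.generatePuncta <- function(spec, rate, factor) {
  pp <- spec@punctaParams
  d <- spec@gridShape
  sp <- spec@spacing
  field <- array(0, d)
  empty <- data.frame(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      intended_sum = numeric(), emitted_total = numeric())
  if (pp$density <= 0) return(list(field = field, puncta = empty))
  vol <- psmDomainVolume(spec)
  n <- rpois(1L, pp$density * vol)
  if (n == 0L) return(list(field = field, puncta = empty))
  domIdx <- which(rate > 0)
  if (!length(domIdx)) return(list(field = field, puncta = empty))
  co <- .axisCoords(spec)
  if (pp$minSeparationRadii > 0) {
    # hard-core rejection sampling, positions uniform over rate-positive voxels
    scale <- c(4, 2, 2) * pp$minSeparationRadii  # z, y, x exclusion semi-axes
    acc <- matrix(numeric(), 0, 3)
    tries <- 0L
    while (nrow(acc) < n && tries < 50L * n) {
      tries <- tries + 1L
      i <- domIdx[sample.int(length(domIdx), 1L)]
      ai <- arrayInd(i, d)
      pos <- c(co[[1]][ai[1]], co[[2]][ai[2]], co[[3]][ai[3]]) +
        (runif(3) - 0.5) * sp
      if (nrow(acc)) {
        u <- sweep(acc, 2, pos)
        if (min(rowSums(sweep(u, 2, scale, `/`)^2)) < 1) next
      }
      acc <- rbind(acc, pos)
    }
    pos <- acc
    n <- nrow(pos)
  } else {
    i <- domIdx[sample.int(length(domIdx), n, replace = TRUE,
                           prob = rate[domIdx])]
    ai <- arrayInd(i, d)
    pos <- cbind(co[[1]][ai[, 1]], co[[2]][ai[, 2]], co[[3]][ai[, 3]]) +
      (matrix(runif(3L * n), n, 3L) - 0.5) *
        matrix(sp, n, 3L, byrow = TRUE)
  }
  intended <- .drawIntendedSums(n, pp)
  emitted <- factor * intended / pp$captureFraction
  sig <- c(pp$sigmaAxial, pp$sigmaLateral, pp$sigmaLateral)
  rad <- pmax(1L, ceiling(3.5 * sig / sp))
  pointLike <- all(3.5 * sig / sp < 0.75)
  for (k in seq_len(n)) {
    if (pointLike) {
      vi <- pmin(pmax(round(pos[k, ] / sp + 0.5), 1L), d)
      field[vi[1], vi[2], vi[3]] <- field[vi[1], vi[2], vi[3]] + emitted[k]
    } else {
      ctr <- round(pos[k, ] / sp + 0.5)
      rng <- lapply(1:3, function(ax)
        max(1L, ctr[ax] - rad[ax]):min(d[ax], ctr[ax] + rad[ax]))
      w1 <- lapply(1:3, function(ax)
        exp(-(co[[ax]][rng[[ax]]] - pos[k, ax])^2 / (2 * sig[ax]^2)))
      w <- outer(w1[[1]], outer(w1[[2]], w1[[3]]))
      w <- w / sum(w)
      field[rng[[1]], rng[[2]], rng[[3]]] <-
        field[rng[[1]], rng[[2]], rng[[3]]] + emitted[k] * w
    }
  }
  list(field = field,
       puncta = data.frame(z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                           intended_sum = intended, emitted_total = emitted))
}

# Forward noise model: scaled Poisson shot noise on the vignetted intensity,
# plus Gaussian read noise and a constant camera baseline, clamped at zero.
.applyNoise <- function(v, np) {
  d <- dim(v)
  n <- length(v)
  if (np$poissonGain > 0) {
    v <- np$poissonGain * rpois(n, as.vector(v) / np$poissonGain)
  }
  if (np$readSd > 0) v <- v + rnorm(n, 0, np$readSd)
  out <- pmax(v + np$baseline, 0)
  dim(out) <- d
  out
}

#' Generate one synthetic embryo phantom
#'
#' Builds the noiseless reference (Tbx6-like), target (Hes7-like striped) and
#' intron-puncta channels, applies the genotype intensity factor, the
#' multiplicative vignette and the Poisson + Gaussian noise model, and
#' returns both the observed image and the full ground truth. Identical
#' spec and seed give bit-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param genotype genotype label; must be a name of
#'   \code{spec@genotypeEffects}.
#' @param sampleId sample identifier stored in the image.
#' @return list with elements \code{image} (\linkS4class{EmbryoImage}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' res <- generateEmbryo(defaultEmbryoSpec(phase = "I", seed = 1))
#' maskVolume(res$truth@referenceMask)
#' @export
generateEmbryo <- function(spec, genotype = "control", sampleId = "sample") {
  validObject(spec)
  if (!genotype %in% names(spec@genotypeEffects)) {
    stop("unknown genotype '", genotype, "'")
  }
  sp <- spec@stripeParams
  lay <- .phaseStripeLayout(sp$phase)
  if (!is.null(sp$count) && sp$count != nrow(lay)) {
    stop("invalid phase/stripe combination: phase ", sp$phase, " implies ",
         nrow(lay), " stripes, got ", sp$count)
  }
  factor <- unname(spec@genotypeEffects[genotype])
  .withSeed(spec@seed, {
    dom <- .psmDomain(spec)
    truthStripes <- .stripeTruth(spec)
    refField <- spec@psmGeometry$refIntensity * dom
    stripe2D <- .stripeModulation(spec, truthStripes)
    targetStructure <- dom * (sp$floor +
      (sp$peak - sp$floor) * .broadcastYX(stripe2D, spec@gridShape[1]))
    targetField <- factor * (targetStructure + .offtargetField(spec))
    intronRate <- dom * (sp$intronFloorFrac +
      .broadcastYX(stripe2D, spec@gridShape[1]))
    pn <- .generatePuncta(spec, intronRate, factor)
    gain3 <- .broadcastYX(.vignetteGain2D(spec), spec@gridShape[1])
    np <- spec@noiseParams
    chans <- list(
      reference = .applyNoise(refField * gain3, np),
      target = .applyNoise(targetField * gain3, np),
      intron_puncta = .applyNoise(pn$field * gain3, np))
    grids <- lapply(names(chans), function(nm)
      VoxelGrid(chans[[nm]], spec@spacing, channel = nm))
    names(grids) <- names(chans)
    image <- new("EmbryoImage", channels = grids, sampleId = sampleId,
                 genotype = genotype, phase = sp$phase)
    truth <- new("GroundTruth",
                 referenceMask = Mask3D(dom, spec@spacing,
                                        provenance = list(method = "ground_truth")),
                 channels = list(reference = refField, target = targetField,
                                 intron_puncta = pn$field),
                 stripes = truthStripes, phase = sp$phase, puncta = pn$puncta,
                 genotypeFactor = factor, genotype = genotype)
    list(image = image, truth = truth)
  })
}

#' Generate a per-channel flat-field stack
#'
#' Emulates the median flat-field stacks acquired from uniform dye
#' solutions: the phantom's multiplicative vignette gain sampled with small
#' Gaussian dye-level noise, clamped to (0, 1].
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param channel channel name (seeds the dye-noise stream so each channel's
#'   flat field is an independent acquisition).
#' @param nz number of z planes to emit (defaults to the spec's grid).
#' @return A \linkS4class{VoxelGrid} of gains in (0, 1].
#' @export
generateFlatfield <- function(spec, channel = "reference",
                              nz = spec@gridShape[1]) {
  g2 <- .vignetteGain2D(spec)
  chOff <- sum(utf8ToInt(channel)) %% 997L
  .withSeed(spec@seed + 7919L * (1L + chOff), {
    a <- .broadcastYX(g2, nz)
    sdn <- spec@vignetteParams$flatfieldNoiseSd
    if (sdn > 0) a <- a + rnorm(length(a), 0, sdn)
    VoxelGrid(pmin(pmax(a, 1e-6), 1), spec@spacing, channel = channel)
  })
}

#' Generate a genotype cohort of phantoms
#'
#' Per-sample seeds are \code{baseSeed + 0:(n-1)}; unless \code{phases} is
#' given, each sample's oscillation phase is drawn uniformly from
#' \{I, II, III\}. Optionally writes each channel stack, a ground-truth JSON
#' sidecar and a CSV manifest to \code{dir}.
#'
#' @param spec a \linkS4class{SyntheticSpec} (its seed is overridden per
#'   sample).
#' @param genotypeCounts named integer vector, genotype -> number of embryos.
#' @param baseSeed integer base seed.
#' @param phases optional character vector of fixed phase labels, recycled
#'   over samples.
#' @param dir optional output directory.
#' @return list with \code{samples} (list of \code{list(image, truth)}) and
#'   \code{manifest} (data.frame: sample_id, genotype, phase, seed, and file
#'   paths when \code{dir} is given).
#' @export
generateCohort <- function(spec, genotypeCounts, baseSeed = 0L, phases = NULL,
                           dir = NULL) {
  bad <- setdiff(names(genotypeCounts), names(spec@genotypeEffects))
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  if (is.null(names(genotypeCounts)) || any(genotypeCounts < 1)) {
    stop("'genotypeCounts' must be a named vector of positive counts")
  }
  nTot <- sum(genotypeCounts)
  genos <- rep(names(genotypeCounts), genotypeCounts)
  phs <- if (is.null(phases)) {
    .withSeed(baseSeed, sample(c("I", "II", "III"), nTot, replace = TRUE))
  } else rep_len(phases, nTot)
  samples <- vector("list", nTot)
  man <- data.frame(sample_id = sprintf("%s_%02d", genos, seq_len(nTot)),
                    genotype = genos, phase = phs,
                    seed = baseSeed + seq_len(nTot) - 1L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nTot)) {
    si <- spec
    si@seed <- as.integer(man$seed[i])
    si@stripeParams$phase <- phs[i]
    samples[[i]] <- generateEmbryo(si, genotype = genos[i],
                                   sampleId = man$sample_id[i])
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ch in c("reference", "target", "intron_puncta")) {
      man[[paste0("path_", ch)]] <- file.path(dir,
        paste0(man$sample_id, "_", ch, ".tif"))
    }
    for (i in seq_len(nTot)) {
      for (ch in c("reference", "target", "intron_puncta")) {
        writeStack(getChannel(samples[[i]]$image, ch),
                   man[[paste0("path_", ch)]][i])
      }
      tr <- samples[[i]]$truth
      jsonlite::write_json(list(
        sample_id = man$sample_id[i], genotype = tr@genotype,
        phase = tr@phase, genotype_factor = tr@genotypeFactor,
        true_mask_volume_um3 = maskVolume(tr@referenceMask),
        stripes = tr@stripes, puncta = tr@puncta),
        file.path(dir, paste0(man$sample_id[i], "_truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = man)
}
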