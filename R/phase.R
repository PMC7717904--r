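# Oscillation-phase analysis: AP expression profiles inside the PSM mask,
# transverse stripe detection with mediolateral extent measurement, the
# three-phase classification rule, and the trough-to-peak metric for
# nascent-transcription signal.

#' Anterior-posterior expression profile within a mask
#'
#' Mean masked intensity per AP bin. The identity
#' \code{sum(profile$mean * profile$n) == } masked intensity sum holds
#' exactly.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param mask a non-empty \linkS4class{Mask3D} of the same shape.
#' @param binWidth AP bin width in um (default 9).
#' @return data.frame with \code{ap_mid_um}, \code{mean}, \code{sum},
#'   \code{n} (masked voxels per bin), restricted to bins containing masked
#'   voxels.
#' @export
apProfile <- function(grid, mask, binWidth = 9) {
  stopifnot(is(grid, "VoxelGrid"), is(mask, "Mask3D"), binWidth > 0)
  if (!identical(dim(grid@data), dim(mask@data))) stop("shape mismatch")
  if (!any(mask@data)) stop("mask is empty")
  d <- dim(grid@data)
  idx <- which(mask@data)
  xIdx <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  xUm <- (xIdx - 0.5) * grid@spacing[3]
  bin <- floor(xUm / binWidth)
  sums <- rowsum(grid@data[idx], bin)
  ns <- rowsum(rep(1L, length(idx)), bin)
  b <- as.numeric(rownames(sums))
  data.frame(ap_mid_um = (b + 0.5) * binWidth, mean = sums[, 1] / ns[, 1],
             sum = sums[, 1], n = ns[, 1], row.names = NULL)
}

# ML extent (um) of signal at half-peak height on a z/x maximum-intensity
# projection restricted to an AP window; span is first-to-last crossing.
.mlExtent <- function(a, maskArr, spacing, xRange, level = 0.5) {
  d <- dim(a)
  xi <- which(((seq_len(d[3]) - 0.5) * spacing[3]) >= xRange[1] &
              ((seq_len(d[3]) - 0.5) * spacing[3]) <= xRange[2])
  if (!length(xi)) return(c(signal = 0, mask = 0))
  sub <- a[, , xi, drop = FALSE] * maskArr[, , xi, drop = FALSE]
  mip <- apply(sub, 2, max)                       # ML profile of the signal
  mMip <- apply(maskArr[, , xi, drop = FALSE], 2, any)
  if (!any(mMip)) return(c(signal = 0, mask = 0))
  # signal span at half height above the profile floor, within mask columns
  base <- min(mip[mMip])
  thr <- base + level * (max(mip[mMip]) - base)
  onS <- which(mMip & mip > thr)
  onM <- which(mMip)
  spanOf <- function(on) if (!length(on)) 0 else
    (on[length(on)] - on[1] + 1L) * spacing[2]
  c(signal = spanOf(onS), mask = spanOf(onM))
}

#' Detect transverse expression stripes
#'
#' Peaks of the lightly smoothed AP profile. Peaks with prominence at least
#' \code{prominenceFrac} of the profile range, separated by at least
#' \code{minSeparation} um, are full stripes; peaks with prominence between
#' \code{initiatingProminenceFrac} and \code{prominenceFrac} of the range
#' located in the posterior \code{posteriorFrac} of the mask are initiating
#' stripes. Each stripe's mediolateral extent is measured at half-peak
#' height on a maximum-intensity projection restricted to its AP window and
#' expressed as a fraction of the mask's ML span there.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param mask a \linkS4class{Mask3D}.
#' @param prominenceFrac full-stripe prominence threshold as a fraction of
#'   the profile range (default 0.2).
#' @param minSeparation minimal AP separation between stripes in um
#'   (default 40).
#' @param binWidth AP profile bin width in um.
#' @param fMid midline-limited ML fraction threshold (default 0.4).
#' @param deltaAnteriorFrac anterior-boundary tolerance as a fraction of the
#'   mask AP length (default 0.05).
#' @param initiatingProminenceFrac lower prominence bound for initiating
#'   stripes (default 0.05).
#' @param posteriorFrac posterior fraction of the mask in which initiating
#'   stripes may sit (default 0.15).
#' @param profileSmoothBins Gaussian sigma (in bins) used to smooth the
#'   profile before peak finding (default 1.5).
#' @return A \linkS4class{StripeSet} (possibly with zero stripes).
#' @export
detectStripes <- function(grid, mask, prominenceFrac = 0.2, minSeparation = 40,
                          binWidth = 9, fMid = 0.4, deltaAnteriorFrac = 0.05,
                          initiatingProminenceFrac = 0.05,
                          posteriorFrac = 0.15, profileSmoothBins = 1.5) {
  prof <- apProfile(grid, mask, binWidth)
  p <- prof$mean
  if (profileSmoothBins > 0 && length(p) > 3L) {
    k <- .gaussKernel1D(profileSmoothBins)
    r <- (length(k) - 1L) %/% 2L
    n <- length(p)
    ii <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    pp <- p[ii]
    p <- as.vector(stats::filter(pp, k, sides = 2))[(r + 1L):(r + n)]
  }
  prof$smoothed <- p
  apMin <- min(prof$ap_mid_um) - binWidth / 2
  apMax <- max(prof$ap_mid_um) + binWidth / 2
  apLen <- apMax - apMin
  rng <- diff(range(p))
  pk <- .peakProminences(p)
  params <- list(prominenceFrac = prominenceFrac, minSeparation = minSeparation,
                 binWidth = binWidth, fMid = fMid,
                 deltaAnteriorFrac = deltaAnteriorFrac,
                 initiatingProminenceFrac = initiatingProminenceFrac,
                 posteriorFrac = posteriorFrac)
  emptySet <- new("StripeSet",
                  stripes = data.frame(ap_center_um = numeric(),
                                       ap_width_um = numeric(),
                                       height = numeric(),
                                       prominence = numeric(),
                                       ml_extent_fraction = numeric(),
                                       is_full = logical(),
                                       reaches_anterior_boundary = logical(),
                                       posterior_midline_limited = logical(),
                                       initiating_at_posterior_midline = logical()),
                  profile = prof, apRange = c(apMin, apMax), params = params)
  if (rng <= 0 || nrow(pk) == 0L) return(emptySet)
  pk$ap_um <- prof$ap_mid_um[pk$index]
  full <- pk[pk$prominence >= prominenceFrac * rng, , drop = FALSE]
  # enforce minimal separation, keeping the more prominent stripe
  if (nrow(full) > 1L) {
    o <- order(full$prominence, decreasing = TRUE)
    kept <- integer()
    for (i in o) {
      if (!length(kept) ||
          min(abs(full$ap_um[kept] - full$ap_um[i])) >= minSeparation) {
        kept <- c(kept, i)
      }
    }
    full <- full[sort(kept), , drop = FALSE]
  }
  init <- pk[pk$prominence >= initiatingProminenceFrac * rng &
             pk$prominence < prominenceFrac * rng &
             pk$ap_um >= apMax - posteriorFrac * apLen, , drop = FALSE]
  if (nrow(init) && nrow(full)) {
    far <- vapply(init$ap_um, function(x)
      min(abs(full$ap_um - x)) >= minSeparation, logical(1))
    init <- init[far, , drop = FALSE]
  }
  allPk <- rbind(cbind(full, is_full = if (nrow(full)) TRUE else logical(0)),
                 cbind(init, is_full = if (nrow(init)) FALSE else logical(0)))
  if (nrow(allPk) == 0L) return(emptySet)
  allPk <- allPk[order(allPk$ap_um), , drop = FALSE]
  widths <- vapply(seq_len(nrow(allPk)), function(i) {
    with(allPk[i, ], .peakWidthAt(p, index, height - prominence / 2, binWidth))
  }, numeric(1))
  mls <- t(vapply(seq_len(nrow(allPk)), function(i) {
    w <- max(widths[i], binWidth)
    .mlExtent(grid@data, mask@data, grid@spacing,
              c(allPk$ap_um[i] - w, allPk$ap_um[i] + w))
  }, numeric(2)))
  mlFrac <- ifelse(mls[, 2] > 0, pmin(mls[, 1] / mls[, 2], 1), 0)
  nFullIdx <- which(allPk$is_full)
  postFull <- if (length(nFullIdx)) max(nFullIdx) else NA_integer_
  stripes <- data.frame(
    ap_center_um = allPk$ap_um,
    ap_width_um = widths,
    height = allPk$height,
    prominence = allPk$prominence,
    ml_extent_fraction = mlFrac,
    is_full = allPk$is_full,
    reaches_anterior_boundary =
      (allPk$ap_um - widths / 2) <= apMin + deltaAnteriorFrac * apLen,
    posterior_midline_limited = FALSE,
    initiating_at_posterior_midline = !allPk$is_full &
      allPk$ap_um >= apMax - posteriorFrac * apLen & mlFrac <= fMid)
  if (!is.na(postFull)) {
    stripes$posterior_midline_limited[postFull] <- mlFrac[postFull] <= fMid
  }
  new("StripeSet", stripes = stripes, profile = prof,
      apRange = c(apMin, apMax), params = params)
}

#' Classify the oscillation phase of a striped expression pattern
#'
#' Snapshot classification at the 5-6 somite stage. Rule order:
#' (a) three full stripes, the posterior-most limited to the posterior
#' midline and the anterior-most reaching the anterior mask boundary ->
#' phase I; (b) two full stripes plus a stripe initiating at the posterior
#' midline -> phase III; (c) two full stripes with the posterior stripe
#' laterally expanded (ML fraction above the midline threshold) and the
#' anterior stripe away from the anterior boundary -> phase II; anything
#' else is unclassifiable. Every predicate tested is recorded in the trace.
#'
#' @param stripes a \linkS4class{StripeSet} from \code{\link{detectStripes}}.
#' @param mask the \linkS4class{Mask3D} the stripes were measured in
#'   (unused beyond provenance; the StripeSet already carries mask-relative
#'   quantities).
#' @return A \linkS4class{PhaseCall}.
#' @export
classifyPhase <- function(stripes, mask = NULL) {
  st <- stripes@stripes
  full <- st[st$is_full, , drop = FALSE]
  nFull <- nrow(full)
  hasInitiating <- any(st$initiating_at_posterior_midline & !st$is_full)
  postLimited <- nFull > 0 && full$posterior_midline_limited[nFull]
  antReaches <- nFull > 0 && full$reaches_anterior_boundary[1]
  postExpanded <- nFull > 0 &&
    full$ml_extent_fraction[nFull] > stripes@params$fMid
  trace <- list(n_full_stripes = nFull,
                posterior_midline_limited = postLimited,
                anterior_reaches_boundary = antReaches,
                posterior_laterally_expanded = postExpanded,
                initiating_at_posterior_midline = hasInitiating)
  phase <- if (nFull == 3L && postLimited && antReaches) "I"
    else if (nFull == 2L && hasInitiating) "III"
    else if (nFull == 2L && postExpanded && !antReaches) "II"
    else "unclassifiable"
  new("PhaseCall", phase = phase, stripeCount = as.integer(nFull),
      criteriaTrace = trace)
}

#' Trough-to-peak metric of the AP profile
#'
#' Depth of the expression minimum between the two most prominent adjacent
#' stripes: the minimum of the AP profile between their centers divided by
#' the mean of the two peak heights. Lies in [0, 1] for non-negative
#' profiles; 1 means no trough, 0 a fully cleared trough. Requires at least
#' two detected stripes.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param mask a \linkS4class{Mask3D}.
#' @param ... passed to \code{\link{detectStripes}}.
#' @return the trough ratio (numeric scalar).
#' @export
troughPeakMetric <- function(grid, mask, ...) {
  ss <- detectStripes(grid, mask, ...)
  st <- ss@stripes[ss@stripes$is_full, , drop = FALSE]
  if (nrow(st) < 2L) stop("fewer than 2 stripes detected")
  pairScore <- st$prominence[-nrow(st)] + st$prominence[-1]
  i <- which.max(pairScore)
  prof <- ss@profile
  between <- prof$ap_mid_um >= st$ap_center_um[i] &
             prof$ap_mid_um <= st$ap_center_um[i + 1L]
  trough <- min(prof$smoothed[between])
  trough / mean(c(st$height[i], st$height[i + 1L]))
}
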