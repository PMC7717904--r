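# Internal numerical helpers shared across modules.
# Arrays are always indexed (z, y, x); spacing vectors are named c(z=, y=, x=) in um.

.AXES <- c("z", "y", "x")

.checkSpacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive finite values (z, y, x) in um")
  }
  spacing <- as.numeric(spacing)
  names(spacing) <- .AXES
  spacing
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Normalized 1D Gaussian kernel for a sigma given in voxels; truncated at ~3.5 sigma.
.gaussKernel1D <- function(sigmaVox) {
  if (sigmaVox < 1e-3) return(1)
  r <- max(1L, ceiling(3.5 * sigmaVox))
  k <- exp(-(seq(-r, r)^2) / (2 * sigmaVox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a symmetric 1D kernel, reflecting at
# the borders (keeps a flat field exactly flat up to the edge).
.convolveAxis <- function(a, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(a * k)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  dim(ap) <- c(n, prod(d[-axis]))
  ii <- seq_len(n + 2L * r) - r
  ii <- ifelse(ii < 1L, 2L - ii, ii)
  ii <- ifelse(ii > n, 2L * n - ii, ii)
  ii <- pmin(pmax(ii, 1L), n)
  pad <- ap[ii, , drop = FALSE]
  out <- 0
  for (j in seq_len(nk)) {
    out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Separable anisotropic Gaussian smoothing at a physical scale (um per axis).
.gaussianSmooth3D <- function(a, sigmaUm, spacing) {
  sigmaUm <- rep_len(sigmaUm, 3L)
  for (ax in 1:3) {
    a <- .convolveAxis(a, .gaussKernel1D(sigmaUm[ax] / spacing[ax]), ax)
  }
  a
}

# Shift a 3D array by (dz, dy, dx), filling exposed borders.
.shift3D <- function(a, dz, dy, dx, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    if (s >= 0) list(dst = seq_len(n - s) + s, src = seq_len(n - s))
    else list(dst = seq_len(n + s), src = seq_len(n + s) - s)
  }
  z <- src(d[1], dz); y <- src(d[2], dy); x <- src(d[3], dx)
  out[z$dst, y$dst, x$dst] <- a[z$src, y$src, x$src]
  out
}

# Strict 26-neighborhood local maxima above a threshold. Ties on plateaus are
# broken lexicographically so a flat-topped blob yields a single maximum.
.localMaxima3D <- function(a, threshold) {
  keep <- a > threshold
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0L && dy == 0L && dx == 0L) next
    if (!any(keep)) break
    s <- .shift3D(a, dz, dy, dx)
    keep <- keep & if (dz > 0L || (dz == 0L && (dy > 0L || (dy == 0L && dx > 0L))))
      a >= s else a > s
  }
  which(keep, arr.ind = TRUE)
}

# Prominence of every local maximum of a 1D profile (scipy-style definition):
# for each peak, walk left and right to the nearest strictly higher sample (or
# the profile end); the bases are the minima over those stretches and the
# prominence is peak height minus the higher base.
.peakProminences <- function(p) {
  n <- length(p)
  empty <- data.frame(index = integer(), height = numeric(),
                      prominence = numeric())
  if (n < 3L) return(empty)
  isPeak <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (p[i] > p[i - 1L]) {
      j <- i                      # absorb a flat plateau top
      while (j < n && p[j + 1L] == p[i]) j <- j + 1L
      if (j < n && p[j + 1L] < p[i]) {
        isPeak <- c(isPeak, as.integer((i + j) %/% 2L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(isPeak)) return(empty)
  prom <- vapply(isPeak, function(i) {
    h <- p[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && p[j] <= h) { lmin <- min(lmin, p[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && p[j] <= h) { rmin <- min(rmin, p[j]); j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = isPeak, height = p[isPeak], prominence = prom)
}

# Width of a peak at a given height: linear-interpolated crossing points of the
# profile around peak index i.
.peakWidthAt <- function(p, i, level, binWidth) {
  n <- length(p)
  l <- i
  while (l > 1L && p[l - 1L] >= level) l <- l - 1L
  left <- if (l == 1L || p[l] <= level) l else
    l - (p[l] - level) / (p[l] - p[l - 1L])
  r <- i
  while (r < n && p[r + 1L] >= level) r <- r + 1L
  right <- if (r == n || p[r] <= level) r else
    r + (p[r] - level) / (p[r] - p[r + 1L])
  (right - left) * binWidth
}
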