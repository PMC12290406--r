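# Seeded synthetic fixtures: brain-like phantoms, band-limited phantoms, the
# benchmark mask families, and the Hadamard corruption model.

#' Generate a smooth brain-like phantom
#'
#' A grayscale phantom of `complexity` nested, jittered, rotated ellipses with
#' distinct interior intensities (outer shell mimicking a skull, inner
#' structures mimicking tissue regions), plus low-amplitude smooth texture,
#' lightly blurred. Deterministic given `seed`; values in [0,1].
#'
#' @param height,width image size, >= 16.
#' @param complexity number of nested ellipses, >= 1.
#' @param seed integer seed.
#' @return height x width matrix in [0,1].
#' @export
generatePhantom <- function(height, width, complexity = 3L, seed = 1L) {
  if (height < 16L || width < 16L) stop("phantom must be at least 16x16")
  if (complexity < 1L) stop("complexity must be >= 1")
  withSeed(seed, {
    yy <- matrix(seq(-1, 1, length.out = height), height, width)
    xx <- matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE)
    img <- matrix(0.05, height, width)
    cx <- stats::runif(1, -0.08, 0.08)
    cy <- stats::runif(1, -0.08, 0.08)
    # intensity levels spaced so adjacent regions differ visibly
    levels <- seq(0.85, 0.25, length.out = complexity) +
      stats::runif(complexity, -0.05, 0.05)
    for (k in seq_len(complexity)) {
      shrink <- 0.85^(k - 1)
      a <- 0.75 * shrink * stats::runif(1, 0.85, 1.05)
      b <- 0.6 * shrink * stats::runif(1, 0.85, 1.05)
      th <- stats::runif(1, -pi / 6, pi / 6)
      jx <- cx + stats::runif(1, -0.05, 0.05) * (k - 1)
      jy <- cy + stats::runif(1, -0.05, 0.05) * (k - 1)
      u <- (xx - jx) * cos(th) + (yy - jy) * sin(th)
      v <- -(xx - jx) * sin(th) + (yy - jy) * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- levels[k]
    }
    # low-amplitude smooth texture
    tex <- lowpassProject(matrix(stats::rnorm(height * width), height, width),
                          min(1, 64 / (height * width) + 0.02))
    if (stats::sd(tex) > 0) tex <- tex / stats::sd(tex)
    img <- img + 0.03 * tex
    img <- conv2same(img, blurKernel5())
    clip01(img)
  })
}

#' Generate a band-limited phantom
#'
#' Seeded white noise projected onto the centred Fourier passband of
#' `passbandFraction` of coefficients, then min-max rescaled to [0,1] (an
#' affine change, so the spectral support is preserved). Outside the passband
#' the discrete Fourier coefficients are exactly zero.
#'
#' @param height,width image size.
#' @param passbandFraction fraction of kept Fourier coefficients, (0,1].
#' @param seed integer seed.
#' @return height x width matrix in [0,1].
#' @export
generateBandlimitedPhantom <- function(height, width, passbandFraction = 0.2,
                                       seed = 1L) {
  if (height < 8L || width < 8L) stop("phantom must be at least 8x8")
  withSeed(seed, {
    z <- matrix(stats::rnorm(height * width), height, width)
    x <- lowpassProject(z, passbandFraction)
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
    x
  })
}

# Achieved mask coverage: fraction of missing (0) cells.
maskCoverage <- function(mask) mean(mask == 0)

#' Generate a binary mask from a family specification
#'
#' Families (1 = observed, 0 = missing):
#' \describe{
#'   \item{bottom}{the bottom `round(target*H)` rows; coverage exact up to row
#'     rounding.}
#'   \item{vrect}{a full-height vertical rectangle on a seeded side; coverage
#'     exact up to column rounding.}
#'   \item{square}{a centred axis-aligned square of side
#'     `round(sqrt(target*H*W))`.}
#'   \item{chin}{a seeded irregular blob centred in the lower-middle region,
#'     with its radius scaled to meet the target coverage.}
#'   \item{freeform}{seeded random brush strokes stamped until the target
#'     coverage is reached.}
#' }
#' Achieved coverage is within about 0.03 of the target for every family.
#'
#' @param spec a [MaskSpec-class].
#' @param height,width canvas size.
#' @return height x width matrix in {0,1}.
#' @export
generateMask <- function(spec, height, width) {
  stopifnot(is(spec, "MaskSpec"))
  validObject(spec)
  tc <- spec@targetCoverage
  mask <- matrix(1, height, width)
  switch(spec@family,
    bottom = {
      nrows <- round(tc * height)
      if (nrows >= 1) mask[(height - nrows + 1L):height, ] <- 0
    },
    vrect = {
      ncols <- round(tc * width)
      if (ncols > width) stop("vrect coverage target unreachable")
      left <- withSeed(spec@seed, stats::runif(1) < 0.5)
      if (ncols >= 1) {
        if (left) mask[, seq_len(ncols)] <- 0
        else mask[, (width - ncols + 1L):width] <- 0
      }
    },
    square = {
      side <- round(sqrt(tc * height * width))
      if (side > min(height, width))
        stop("square coverage target unreachable on this canvas")
      r0 <- floor((height - side) / 2) + 1L
      c0 <- floor((width - side) / 2) + 1L
      mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 0
    },
    chin = mask <- withSeed(spec@seed, chinMask(height, width, tc)),
    freeform = mask <- withSeed(spec@seed, freeformMask(height, width, tc)),
    stop("unknown mask family"))
  mask
}

# Irregular blob centred in the lower-middle region: an ellipse whose radius is
# modulated by a few random angular harmonics, scaled to hit the coverage.
chinMask <- function(height, width, target) {
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- 0.72 * height
  cx <- 0.5 * width
  dy <- (yy - cy) / height
  dx <- (xx - cx) / width
  ang <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  amp <- stats::runif(3, 0.05, 0.18)
  ph <- stats::runif(3, 0, 2 * pi)
  mod <- 1 + amp[1] * cos(2 * ang + ph[1]) + amp[2] * cos(3 * ang + ph[2]) +
    amp[3] * cos(5 * ang + ph[3])
  # monotone in the scale: bisect the base radius to meet the target coverage
  lo <- 0.01; hi <- 0.9
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    cov <- mean(r <= mid * mod)
    if (cov < target) lo <- mid else hi <- mid
  }
  mask <- matrix(1, height, width)
  mask[r <= ((lo + hi) / 2) * mod] <- 0
  mask
}

# Random brush strokes: persistent random walks stamped with a disk, until the
# target coverage is reached.
freeformMask <- function(height, width, target) {
  mask <- matrix(1, height, width)
  brush <- max(2L, round(min(height, width) / 18))
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  stamp <- function(m, y, x) {
    m[(yy - y)^2 + (xx - x)^2 <= brush^2] <- 0
    m
  }
  guard <- 0L
  while (maskCoverage(mask) < target - 0.005 && guard < 10000L) {
    y <- stats::runif(1, 1, height)
    x <- stats::runif(1, 1, width)
    th <- stats::runif(1, 0, 2 * pi)
    nsteps <- sample(5:15, 1)
    for (s in seq_len(nsteps)) {
      mask <- stamp(mask, y, x)
      if (maskCoverage(mask) >= target) break
      th <- th + stats::rnorm(1, 0, 0.5)
      y <- min(max(y + brush * sin(th), 1), height)
      x <- min(max(x + brush * cos(th), 1), width)
      guard <- guard + 1L
    }
  }
  mask
}

#' Corrupt a clean image with a mask and pixel noise
#'
#' The observation is the Hadamard product mask * clean; additive Gaussian
#' noise with standard deviation `noise@sigmaPixel` is applied only where the
#' mask is 1 and the result is clipped to [0,1]. Masked cells stay exactly 0.
#'
#' @param clean H x W matrix in [0,1].
#' @param mask H x W binary mask (1 = observed).
#' @param noise a [NoiseParams-class].
#' @param seed integer seed for the noise draw.
#' @return a [CorruptedObservation-class].
#' @export
corruptImage <- function(clean, mask, noise = NoiseParams(), seed = 1L) {
  stopifnotMatrix(clean, "clean")
  if (min(clean) < -1e-9 || max(clean) > 1 + 1e-9)
    stop("'clean' intensities must lie in [0,1]")
  checkMask(mask, clean)
  observed <- mask * clean
  if (noise@sigmaPixel > 0) {
    eps <- withSeed(seed, matrix(stats::rnorm(length(clean), 0,
                                              noise@sigmaPixel),
                                 nrow(clean), ncol(clean)))
    observed <- clip01(observed + mask * eps)
    observed[mask == 0] <- 0
  }
  new("CorruptedObservation", observed = observed, mask = mask, noise = noise,
      seed = seed)
}
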