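# Shared fixtures and independent oracles for the test suite.
#
# Expensive objects (the trained phantom decoder and its corpus) are built
# once per session and cached; every oracle here recomputes its quantity by a
# route independent of the implementation it checks (explicit trigonometric
# basis + least squares for band-limited completion, dense normal equations
# for the conjugate affine-Gaussian model).

.testCache <- new.env(parent = emptyenv())

cachedValue <- function(key, builder) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- builder()
  .testCache[[key]]
}

phantomCorpus <- function(n, size = 32L, seedBase = 7000L) {
  cachedValue(sprintf("corpus_%d_%d_%d", n, size, seedBase), function()
    lapply(seq_len(n), function(i)
      generatePhantom(size, size, 3L, seed = seedBase + i)))
}

# Decoder trained on 200 phantoms; reused by generator, pipeline and
# acceptance tests.
trainedPhantomDecoder <- function() {
  cachedValue("decoder200", function()
    trainDecoder(phantomCorpus(200L), c(4L, 16L), epochs = 40L, seed = 101L))
}

heldOutCases <- function(n = 10L, family = "square", sigmaPixel = 0.05,
                         seedBase = 8000L) {
  lapply(seq_len(n), function(i) {
    clean <- generatePhantom(32L, 32L, 3L, seed = seedBase + 500L + i)
    fam <- if (length(family) > 1L)
      family[((i - 1L) %% length(family)) + 1L] else family
    mask <- generateMask(MaskSpec(fam, seed = seedBase + i), 32L, 32L)
    obs <- corruptImage(clean, mask, NoiseParams(sigmaPixel, 1),
                        seed = seedBase + 900L + i)
    list(clean = clean, obs = obs, mask = mask)
  })
}

# ---- band-limited completion oracle ----------------------------------------

# Least-squares band-limited interpolation through an explicit real
# trigonometric basis of the passband (cos/sin pairs per canonical frequency),
# fitted to the observed pixels only. Shares only the passband *set* with the
# implementation; the completion route (basis + QR least squares) is
# independent of the FFT projection iteration it checks.
bandlimitedLeastSquares <- function(observed, mask, fraction) {
  h <- nrow(observed); w <- ncol(observed)
  keep <- passbandIndicator(h, w, fraction)
  kidx <- which(keep, arr.ind = TRUE) - 1L
  sr <- ifelse(kidx[, 1L] <= h %/% 2L, kidx[, 1L], kidx[, 1L] - h)
  sc <- ifelse(kidx[, 2L] <= w %/% 2L, kidx[, 2L], kidx[, 2L] - w)
  canonical <- sr > 0 | (sr == 0 & sc >= 0)
  sr <- sr[canonical]; sc <- sc[canonical]
  ii <- matrix(0:(h - 1L), h, w)
  jj <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  cols <- list()
  for (k in seq_along(sr)) {
    th <- 2 * pi * (sr[k] * ii / h + sc[k] * jj / w)
    cols[[length(cols) + 1L]] <- as.vector(cos(th))
    selfConj <- (2L * sr[k]) %% h == 0L && (2L * sc[k]) %% w == 0L
    if (!selfConj) cols[[length(cols) + 1L]] <- as.vector(sin(th))
  }
  B <- do.call(cbind, cols)
  stopifnot(ncol(B) == sum(keep))
  obsIdx <- which(as.vector(mask) == 1)
  coef <- qr.coef(qr(B[obsIdx, , drop = FALSE]),
                  as.vector(observed)[obsIdx])
  coef[is.na(coef)] <- 0
  matrix(B %*% coef, h, w)
}

# ---- conjugate affine-Gaussian model ---------------------------------------

# A seeded instance of the conjugate model: affine generator, square mask,
# pixel noise. Exposes the pieces needed for closed-form solutions.
conjugateSetup <- function(seed = 1L, latentShape = c(2L, 8L),
                           imageShape = c(16L, 16L), sigmaPixel = 0.05) {
  gen <- linearGenerator(latentShape, imageShape, seed = seed + 10L)
  prior <- LatentPrior(latentShape[1L], latentShape[2L])
  omTrue <- withSeed(seed + 20L,
                     matrix(stats::rnorm(prod(latentShape)), latentShape[1L]))
  clean <- generatorApply(gen, omTrue)
  mask <- generateMask(MaskSpec("square", seed = seed + 30L),
                       imageShape[1L], imageShape[2L])
  obs <- corruptImage(clean, mask, NoiseParams(sigmaPixel, 1),
                      seed = seed + 40L)
  mvec <- as.vector(mask)
  DA <- gen@A * mvec
  c0 <- (gen@scale * gen@b + gen@offset) * mvec
  list(gen = gen, prior = prior, omTrue = omTrue, clean = clean, mask = mask,
       obs = obs, DA = DA, c0 = c0, s = gen@scale,
       a = 1 / (2 * sigmaPixel^2))
}

# MAP solution of lambdaPixel * pixel + lambdaPrior * mean-prior by dense
# normal equations.
conjugateMapOracle <- function(su, lambdaPixel = 1, lambdaPrior = 1) {
  n <- length(su$omTrue)
  a <- lambdaPixel * su$a
  y <- as.vector(su$obs@observed)
  lhs <- 2 * a * su$s^2 * crossprod(su$DA) + diag(2 * lambdaPrior, n)
  as.vector(solve(lhs, 2 * a * su$s * crossprod(su$DA, y - su$c0)))
}

# Exact Gaussian posterior (unit-variance latent prior as in the KL term).
conjugatePosteriorOracle <- function(su, lambdaPixel = 1) {
  n <- length(su$omTrue)
  a <- lambdaPixel * su$a
  y <- as.vector(su$obs@observed)
  P <- diag(1, n) + 2 * a * su$s^2 * crossprod(su$DA)
  Sigma <- solve(P)
  list(mean = as.vector(Sigma %*% (2 * a * su$s * crossprod(su$DA, y - su$c0))),
       var = diag(Sigma), precision = P)
}

# Weights used for the phantom inversion experiments: pixel-dominant data
# term plus the full-prior mode (intensity anchor toward the
# Papoulis-Gerchberg completion).
phantomWeights <- function()
  LossWeights(lambdaPrior = 1e-2, lambdaCosine = 0, lambdaPixel = 1,
              lambdaPercept = 0, lambdaIntensity = 60)

maskedRmse <- function(clean, img, mask)
  sqrt(mean(((clean - img)[mask == 0] * 255)^2))

meanFill <- function(obs) {
  out <- obs@observed
  out[obs@mask == 0] <- mean(obs@observed[obs@mask == 1])
  out
}
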