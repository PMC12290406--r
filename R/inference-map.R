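# MAP inference: the four-term objective (prior + cosine + pixel + perceptual,
# optionally + intensity) and first-order adaptive optimization of the latent
# code. All loss gradients are exact reverse-mode adjoints.

# ---- forward measurement operator ------------------------------------------

# 1-D area-averaging weight matrix (nf x n): row i averages the image interval
# [(i-1)n/nf, i n/nf) with fractional-overlap weights. Linear, hence an exact
# transpose for gradients.
areaWeights <- function(nf, n) {
  W <- matrix(0, nf, n)
  step <- n / nf
  for (i in seq_len(nf)) {
    a <- (i - 1) * step
    b <- i * step
    j0 <- floor(a) + 1L
    j1 <- ceiling(b)
    for (j in j0:min(j1, n)) {
      lo <- max(a, j - 1)
      hi <- min(b, j)
      if (hi > lo) W[i, j] <- (hi - lo) / step
    }
  }
  W
}

#' Forward measurement operator
#'
#' Returns `mask * image`, area-averaged down to an nf x nf grid when
#' `fwd@nf > 0`. Linear in the image.
#'
#' @param image H x W matrix.
#' @param mask H x W binary mask.
#' @param fwd a [ForwardConfig-class].
#' @return H x W matrix (nf = 0) or nf x nf matrix.
#' @export
forwardOperator <- function(image, mask, fwd = ForwardConfig()) {
  sameDim(image, mask, "image and mask")
  x <- mask * image
  nf <- fwd@nf
  if (nf == 0) return(x)
  if (nf > min(dim(image))) stop("nf exceeds the image side")
  Wr <- areaWeights(nf, nrow(x))
  Wc <- areaWeights(nf, ncol(x))
  Wr %*% x %*% t(Wc)
}

# Adjoint of forwardOperator with respect to the image.
forwardOperatorT <- function(g, mask, fwd) {
  nf <- fwd@nf
  if (nf == 0) return(mask * g)
  Wr <- areaWeights(nf, nrow(mask))
  Wc <- areaWeights(nf, ncol(mask))
  mask * (t(Wr) %*% g %*% Wc)
}

# ---- pixel loss -------------------------------------------------------------

#' Pixel-wise data loss
#'
#' Squared L2 distance between the forward measurements of G(omega) and of
#' the observation, divided by 2*sigmaPixel^2 when sigmaPixel > 0 (unscaled
#' when 0).
#'
#' @param omega L x D latent matrix.
#' @param obs a [CorruptedObservation-class].
#' @param generator a [GeneratorModel-class].
#' @param fwd a [ForwardConfig-class].
#' @return nonnegative scalar.
#' @export
pixelLoss <- function(omega, obs, generator, fwd = ForwardConfig()) {
  g <- generatorApply(generator, omega)
  r <- forwardOperator(g, obs@mask, fwd) -
    forwardOperator(obs@observed, obs@mask, fwd)
  sp <- obs@noise@sigmaPixel
  sc <- if (sp > 0) 1 / (2 * sp^2) else 1
  sc * sum(r^2)
}

# Image-space gradient of pixelLoss (before the generator VJP).
pixelLossImageGrad <- function(gImg, obs, fwd) {
  r <- forwardOperator(gImg, obs@mask, fwd) -
    forwardOperator(obs@observed, obs@mask, fwd)
  sp <- obs@noise@sigmaPixel
  sc <- if (sp > 0) 1 / (2 * sp^2) else 1
  forwardOperatorT(2 * sc * r, obs@mask, fwd)
}

# ---- perceptual features ----------------------------------------------------

# Fixed orientation-selective 3x3 kernels, named by the edge orientation they
# respond to (0 = horizontal edge, 90 = vertical edge, and the two diagonals).
orientationKernels <- function() {
  list(
    o0 = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = FALSE) / 4,
    o45 = matrix(c(0, -1, -2, 1, 0, -1, 2, 1, 0), 3, 3, byrow = FALSE) / 4,
    o90 = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = FALSE) / 4,
    o135 = matrix(c(2, 1, 0, 1, 0, -1, 0, -1, -2), 3, 3, byrow = FALSE) / 4)
}

.featEps <- 1e-2

#' Deterministic perceptual feature stack
#'
#' A hand-crafted, weight-free stand-in for a learned perceptual extractor:
#' a 3-level Gaussian pyramid; at each level four orientation-selective
#' gradient responses (0/45/90/135 degrees) from fixed 3x3 kernels, each
#' response normalized by its root-mean-square plus a small epsilon. Fully
#' deterministic.
#'
#' @param image H x W matrix, at least 16 x 16.
#' @return list of levels, each a named list of four response matrices.
#' @export
perceptualFeatures <- function(image) {
  stopifnotMatrix(image, "image")
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("perceptual features need at least a 16x16 image")
  ks <- orientationKernels()
  blur <- blurKernel5()
  levels <- vector("list", 3L)
  x <- image
  for (l in 1:3) {
    responses <- lapply(ks, function(k) {
      r <- conv2rep(x, k)
      r / (sqrt(mean(r^2)) + .featEps)
    })
    levels[[l]] <- responses
    if (l < 3L) x <- down2(conv2rep(x, blur))
  }
  levels
}

# Squared L2 distance between two feature stacks.
featureDistance <- function(fa, fb) {
  total <- 0
  for (l in seq_along(fa))
    for (o in names(fa[[l]]))
      total <- total + sum((fa[[l]][[o]] - fb[[l]][[o]])^2)
  total
}

# Gradient of featureDistance(phi(x), fb) with respect to x: backprop through
# the per-response RMS normalization, the fixed kernels, and the pyramid.
featureDistanceGrad <- function(x, fb) {
  ks <- orientationKernels()
  blur <- blurKernel5()
  pyramid <- list(x)
  for (l in 1:2) pyramid[[l + 1L]] <- down2(conv2rep(pyramid[[l]], blur))
  gLevel <- vector("list", 3L)
  for (l in 1:3) {
    xl <- pyramid[[l]]
    g <- xl * 0
    for (o in names(ks)) {
      r <- conv2rep(xl, ks[[o]])
      s <- sqrt(mean(r^2))
      rn <- r / (s + .featEps)
      gr_n <- 2 * (rn - fb[[l]][[o]])
      # d(r / (s+eps)) adjoint: s = sqrt(mean(r^2))
      inner <- sum(gr_n * r)
      gr <- gr_n / (s + .featEps)
      if (s > 0)
        gr <- gr - r * inner / (length(r) * s * (s + .featEps)^2)
      g <- g + conv2repT(gr, ks[[o]])
    }
    gLevel[[l]] <- g
  }
  # fold pyramid gradients back up: x_{l+1} = down2(blur * x_l)
  g <- gLevel[[3L]]
  for (l in 2:1) {
    gu <- conv2repT(down2T(g, nrow(pyramid[[l]]), ncol(pyramid[[l]])), blur)
    g <- gLevel[[l]] + gu
  }
  g
}

#' Perceptual data loss
#'
#' Squared L2 distance between the feature stacks of mask * G(omega) and of
#' the observed image, divided by 2*sigmaPercept^2 when positive.
#'
#' @inheritParams pixelLoss
#' @return nonnegative scalar.
#' @export
perceptualLoss <- function(omega, obs, generator) {
  g <- generatorApply(generator, omega)
  fa <- perceptualFeatures(obs@mask * g)
  fb <- perceptualFeatures(obs@observed)
  sp <- obs@noise@sigmaPercept
  sc <- if (sp > 0) 1 / (2 * sp^2) else 1
  sc * featureDistance(fa, fb)
}

perceptualLossImageGrad <- function(gImg, obs) {
  fb <- perceptualFeatures(obs@observed)
  sp <- obs@noise@sigmaPercept
  sc <- if (sp > 0) 1 / (2 * sp^2) else 1
  sc * obs@mask * featureDistanceGrad(obs@mask * gImg, fb)
}

# ---- total loss -------------------------------------------------------------

#' Four-term (optionally five-term) total loss
#'
#' lambdaPrior * meanPriorLoss + lambdaCosine * cosinePriorLoss +
#' lambdaPixel * pixelLoss + lambdaPercept * perceptualLoss
#' (+ lambdaIntensity * intensityPriorLoss against `pgImage`).
#'
#' @param omega L x D latent matrix.
#' @param obs a [CorruptedObservation-class].
#' @param generator a [GeneratorModel-class].
#' @param prior a [LatentPrior-class].
#' @param weights a [LossWeights-class].
#' @param fwd a [ForwardConfig-class].
#' @param pgImage Papoulis-Gerchberg completion (required when
#'   `lambdaIntensity > 0`).
#' @return list with `total` and `terms` (each term unweighted and weighted).
#' @export
totalLoss <- function(omega, obs, generator, prior, weights,
                      fwd = ForwardConfig(), pgImage = NULL) {
  gImg <- generatorApply(generator, omega)
  terms <- list()
  addTerm <- function(terms, name, lambda, value) {
    terms[[name]] <- c(unweighted = value, weighted = lambda * value)
    terms
  }
  vPrior <- if (weights@lambdaPrior > 0) meanPriorLoss(omega, prior) else 0
  vCos <- if (weights@lambdaCosine > 0) cosinePriorLoss(omega) else 0
  vPix <- if (weights@lambdaPixel > 0)
    pixelLoss(omega, obs, generator, fwd) else 0
  vPer <- if (weights@lambdaPercept > 0)
    perceptualLoss(omega, obs, generator) else 0
  vInt <- 0
  if (weights@lambdaIntensity > 0) {
    if (is.null(pgImage)) stop("lambdaIntensity > 0 requires pgImage")
    vInt <- intensityPriorLoss(gImg, pgImage, obs@mask)
  }
  terms <- addTerm(terms, "prior", weights@lambdaPrior, vPrior)
  terms <- addTerm(terms, "cosine", weights@lambdaCosine, vCos)
  terms <- addTerm(terms, "pixel", weights@lambdaPixel, vPix)
  terms <- addTerm(terms, "percept", weights@lambdaPercept, vPer)
  terms <- addTerm(terms, "intensity", weights@lambdaIntensity, vInt)
  total <- sum(vapply(terms, function(t) t[["weighted"]], 1))
  list(total = total, terms = terms)
}

# Gradient of the total loss with respect to omega (exact reverse mode).
totalLossGrad <- function(omega, obs, generator, prior, weights,
                          fwd = ForwardConfig(), pgImage = NULL) {
  gImg <- generatorApply(generator, omega)
  gI <- gImg * 0
  if (weights@lambdaPixel > 0)
    gI <- gI + weights@lambdaPixel * pixelLossImageGrad(gImg, obs, fwd)
  if (weights@lambdaPercept > 0)
    gI <- gI + weights@lambdaPercept * perceptualLossImageGrad(gImg, obs)
  if (weights@lambdaIntensity > 0)
    gI <- gI + weights@lambdaIntensity *
      intensityPriorGrad(gImg, pgImage, obs@mask)
  gOmega <- if (any(gI != 0)) generatorVJP(generator, omega, gI)
  else omega * 0
  if (weights@lambdaPrior > 0)
    gOmega <- gOmega + weights@lambdaPrior * meanPriorGrad(omega, prior)
  if (weights@lambdaCosine > 0)
    gOmega <- gOmega + weights@lambdaCosine * cosinePriorGrad(omega)
  gOmega
}

# ---- MAP optimization -------------------------------------------------------

#' MAP inpainting by gradient-based latent optimization
#'
#' Initializes omega ~ N(mu, sigma^2) from the prior (seeded), optionally
#' warm-starts by fitting G(omega) to the Papoulis-Gerchberg completion, then
#' minimizes [totalLoss()] with Adam (defaults: 500 iterations, learning rate
#' 0.001). The reported solution is the best iterate seen; with
#' `composite = TRUE` (default) observed pixels are pasted over the generator
#' output so only masked cells are synthesized.
#'
#' @param obs a [CorruptedObservation-class].
#' @param generator a [GeneratorModel-class].
#' @param prior a [LatentPrior-class] matching the generator latent shape.
#' @param weights a [LossWeights-class].
#' @param fwd a [ForwardConfig-class].
#' @param iterations Adam iterations, >= 1 (default 500).
#' @param lr learning rate (default 0.001).
#' @param seed integer seed for the initialization.
#' @param warmStart run `warmStartIters` iterations fitting the generator
#'   output to the Papoulis-Gerchberg completion before the main objective.
#' @param warmStartIters warm-start iteration count (default 100).
#' @param composite paste observed pixels over the output (default TRUE).
#' @param init initialization: `NULL` for the seeded prior draw; an explicit
#'   latent matrix; or `"nearest"` (decoder generators only) to start from
#'   the training latents whose decoded images best fit the observed region —
#'   retrieval initialization, the encoder-free analogue of encoder-based
#'   generator inversion.
#' @param restarts with `init = "nearest"`, how many top-ranked training
#'   latents to refine; the run with the lowest final loss is reported.
#' @return an [InpaintResult-class].
#' @export
mapInpaint <- function(obs, generator, prior, weights = LossWeights(),
                       fwd = ForwardConfig(), iterations = 500L, lr = 0.001,
                       seed = 1L, warmStart = FALSE, warmStartIters = 100L,
                       composite = TRUE, init = NULL, restarts = 3L) {
  if (is.character(init) && identical(init, "nearest")) {
    if (!is(generator, "DecoderGenerator") ||
        nrow(generator@trainLatents) == 0L)
      stop("init = 'nearest' needs a decoder generator with training latents")
    Z <- generator@trainLatents
    errs <- vapply(seq_len(nrow(Z)), function(i) {
      d <- generatorApply(generator,
                          matrix(Z[i, ], nrow(prior@mu), ncol(prior@mu)))
      sum(((d - obs@observed) * obs@mask)^2)
    }, 1)
    picks <- order(errs)[seq_len(min(restarts, nrow(Z)))]
    best <- NULL
    for (k in picks) {
      res <- mapInpaint(obs, generator, prior, weights, fwd, iterations, lr,
                        seed, warmStart, warmStartIters, composite,
                        init = matrix(Z[k, ], nrow(prior@mu), ncol(prior@mu)))
      fl <- res@lossTrace[length(res@lossTrace)]
      if (is.null(best) || fl < best@lossTrace[length(best@lossTrace)])
        best <- res
    }
    return(best)
  }
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!all(dim(prior@mu) == latentShape(generator)))
    stop("prior shape does not match the generator latent shape")
  omega <- if (!is.null(init)) init else
    withSeed(seed, prior@mu + prior@sigma *
               matrix(stats::rnorm(length(prior@mu)), nrow(prior@mu)))

  pgImage <- NULL
  if (warmStart || weights@lambdaIntensity > 0)
    pgImage <- pgComplete(obs, prior)$image

  if (warmStart && warmStartIters > 0L) {
    st <- NULL
    for (it in seq_len(warmStartIters)) {
      g <- generatorApply(generator, omega)
      gOmega <- generatorVJP(generator, omega, 2 * (g - pgImage))
      up <- adamStep(omega, gOmega, st, lr)
      omega <- up$par
      st <- up$st
    }
  }

  evalLoss <- function(om) totalLoss(om, obs, generator, prior, weights,
                                     fwd, pgImage)
  cur <- evalLoss(omega)
  trace <- numeric(iterations + 2L)
  trace[1L] <- cur$total
  best <- list(omega = omega, loss = cur$total)
  st <- NULL
  for (it in seq_len(iterations)) {
    g <- totalLossGrad(omega, obs, generator, prior, weights, fwd, pgImage)
    if (any(!is.finite(g)))
      stop(sprintf("non-finite gradient at iteration %d", it))
    up <- adamStep(omega, g, st, lr)
    omega <- up$par
    st <- up$st
    cur <- evalLoss(omega)
    if (!is.finite(cur$total))
      stop(sprintf(
        "non-finite loss at iteration %d (terms: %s)", it,
        paste(sprintf("%s=%.3g", names(cur$terms),
                      vapply(cur$terms, function(t) t[["weighted"]], 1)),
              collapse = ", ")))
    trace[it + 1L] <- cur$total
    if (cur$total < best$loss) best <- list(omega = omega, loss = cur$total)
  }
  final <- evalLoss(best$omega)
  trace[iterations + 2L] <- final$total
  raw <- generatorApply(generator, best$omega)
  comp <- if (composite) obs@mask * obs@observed + (1 - obs@mask) * raw
  else raw
  new("InpaintResult", latent = best$omega, rawGenerated = raw,
      composited = comp, perTermLosses = final$terms, lossTrace = trace,
      iterations = as.integer(iterations), seed = seed)
}
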