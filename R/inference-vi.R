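# Per-image Gaussian variational posterior over the latent code, fitted by
# reparameterized Bayes-by-Backprop: closed-form diagonal-Gaussian KL to the
# mean prior plus a Monte-Carlo estimate of the expected data loss.

#' Closed-form KL divergence between diagonal Gaussians
#'
#' KL(q || p) summed over all L*D coordinates, where q has mean/std from the
#' variational parameters and p = N(prior mu, diag(prior sigma^2)). Zero iff
#' q equals the prior.
#'
#' @param q a [VariationalPosterior-class].
#' @param prior a [LatentPrior-class] of matching shape.
#' @return nonnegative scalar.
#' @export
klDiagGaussian <- function(q, prior) {
  sameDim(q@mean, prior@mu, "variational parameters and prior")
  if (any(prior@sigma <= 0)) stop("prior sigma must be positive")
  s <- exp(q@logStd)
  sum(log(prior@sigma) - q@logStd +
        (s^2 + (q@mean - prior@mu)^2) / (2 * prior@sigma^2) - 0.5)
}

klGradMean <- function(m, prior) (m - prior@mu) / prior@sigma^2
klGradLogStd <- function(ls, prior) -1 + exp(2 * ls) / prior@sigma^2

#' Fit the variational posterior by modified Bayes-by-Backprop
#'
#' Minimizes KL(q || prior) + E_q[weighted data loss] over the posterior mean
#' and log standard deviations, the expectation estimated with `mcSamples`
#' reparameterized draws omega = mean + std * eps per iteration. The data
#' loss carries the pixel, perceptual, cosine and (optionally) intensity
#' terms of [totalLoss()]; the mean prior enters through the closed-form KL
#' instead. Defaults: 500 iterations, Adam with learning rate 0.01, one
#' Monte-Carlo sample. The returned parameters are the average over the last
#' `tailAverage` fraction of iterations (plain last iterate when 0), which
#' removes the stationary jitter of constant-step-size Adam.
#'
#' @param obs a [CorruptedObservation-class].
#' @param generator a [GeneratorModel-class].
#' @param prior a [LatentPrior-class].
#' @param weights a [LossWeights-class]; `lambdaPrior` is ignored here (the
#'   KL term plays that role).
#' @param fwd a [ForwardConfig-class].
#' @param iterations optimization iterations (default 500).
#' @param lr Adam learning rate (default 0.01).
#' @param mcSamples Monte-Carlo samples per iteration (default 1).
#' @param seed integer seed.
#' @param tailAverage fraction of final iterations to average (default 0.25).
#' @param init optional [VariationalPosterior-class] or latent matrix used to
#'   initialize the mean (e.g. a MAP solution); default prior mu.
#' @return a fitted [VariationalPosterior-class].
#' @export
bbbFit <- function(obs, generator, prior, weights = LossWeights(),
                   fwd = ForwardConfig(), iterations = 500L, lr = 0.01,
                   mcSamples = 1L, seed = 1L, tailAverage = 0.25,
                   init = NULL) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (mcSamples < 1L) stop("mcSamples must be >= 1")
  m <- if (is.null(init)) prior@mu
  else if (is(init, "VariationalPosterior")) init@mean
  else init
  ls <- log(0.1 * prior@sigma)
  pgImage <- if (weights@lambdaIntensity > 0) pgComplete(obs, prior)$image
  else NULL

  dataWeights <- LossWeights(lambdaPrior = 0,
                             lambdaCosine = weights@lambdaCosine,
                             lambdaPixel = weights@lambdaPixel,
                             lambdaPercept = weights@lambdaPercept,
                             lambdaIntensity = weights@lambdaIntensity)

  trace <- numeric(iterations)
  tailN <- max(1L, floor(tailAverage * iterations))
  mSum <- m * 0
  lsSum <- ls * 0
  tailCount <- 0L
  withSeed(seed, {
    stM <- NULL; stLs <- NULL
    for (it in seq_len(iterations)) {
      s <- exp(ls)
      gM <- klGradMean(m, prior)
      gLs <- klGradLogStd(ls, prior)
      dataVal <- 0
      for (k in seq_len(mcSamples)) {
        eps <- matrix(stats::rnorm(length(m)), nrow(m))
        omega <- m + s * eps
        dOmega <- totalLossGrad(omega, obs, generator, prior, dataWeights,
                                fwd, pgImage)
        if (any(!is.finite(dOmega)))
          stop(sprintf("non-finite objective gradient at iteration %d", it))
        gM <- gM + dOmega / mcSamples
        gLs <- gLs + (dOmega * eps * s) / mcSamples
        dataVal <- dataVal +
          totalLoss(omega, obs, generator, prior, dataWeights, fwd,
                    pgImage)$total / mcSamples
      }
      qNow <- new("VariationalPosterior", mean = m, logStd = ls,
                  fitted = FALSE, seed = seed, elboTrace = numeric(0))
      trace[it] <- klDiagGaussian(qNow, prior) + dataVal
      if (!is.finite(trace[it]))
        stop(sprintf("non-finite objective at iteration %d", it))
      up <- adamStep(m, gM, stM, lr); m <- up$par; stM <- up$st
      up <- adamStep(ls, gLs, stLs, lr); ls <- up$par; stLs <- up$st
      if (it > iterations - tailN) {
        mSum <- mSum + m
        lsSum <- lsSum + ls
        tailCount <- tailCount + 1L
      }
    }
  })
  if (tailAverage > 0 && tailCount > 0L) {
    m <- mSum / tailCount
    ls <- lsSum / tailCount
  }
  new("VariationalPosterior", mean = m, logStd = ls, fitted = TRUE,
      seed = seed, elboTrace = trace)
}

#' Draw posterior reconstructions
#'
#' Draws `n` independent latents omega ~ N(mean, diag(std^2)) from a fitted
#' posterior, decodes each through the generator, and composites observed
#' pixels as in [mapInpaint()].
#'
#' @param q a fitted [VariationalPosterior-class].
#' @param generator a [GeneratorModel-class].
#' @param obs a [CorruptedObservation-class].
#' @param n number of samples, >= 1.
#' @param seed integer seed.
#' @param composite paste observed pixels over each sample (default TRUE).
#' @return list of [InpaintResult-class], one per sample.
#' @export
sampleReconstructions <- function(q, generator, obs, n = 5L, seed = 1L,
                                  composite = TRUE) {
  if (!q@fitted) stop("variational posterior has not been fitted")
  if (n < 1L) stop("n must be >= 1")
  s <- exp(q@logStd)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      omega <- q@mean + s * matrix(stats::rnorm(length(q@mean)), nrow(q@mean))
      raw <- generatorApply(generator, omega)
      comp <- if (composite) obs@mask * obs@observed + (1 - obs@mask) * raw
      else raw
      new("InpaintResult", latent = omega, rawGenerated = raw,
          composited = comp, perTermLosses = list(),
          lossTrace = NA_real_, iterations = 0L, seed = seed)
    })
  })
}
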