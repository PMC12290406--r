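# The three structured prior terms and their combination: diagonal-Gaussian
# mean prior on the latent code, cosine-similarity prior between adjacent
# latent levels, and the Papoulis-Gerchberg band-limited intensity prior.
# Analytic gradients accompany the latent-space terms for the optimizers.

#' Mean (Gaussian) prior loss on the latent code
#'
#' Sum over all L*D entries of ((omega - mu)/sigma)^2: the Gaussian negative
#' log-density up to an additive constant and a factor 2. Zero iff omega = mu.
#'
#' @param omega L x D latent matrix.
#' @param prior a [LatentPrior-class] with matching shape.
#' @return nonnegative scalar.
#' @export
meanPriorLoss <- function(omega, prior) {
  sameDim(omega, prior@mu, "latent code and prior mean")
  if (any(prior@sigma <= 0)) stop("prior sigma must be positive")
  sum(((omega - prior@mu) / prior@sigma)^2)
}

meanPriorGrad <- function(omega, prior)
  2 * (omega - prior@mu) / prior@sigma^2

#' Cosine-similarity prior loss between adjacent latent levels
#'
#' Sum over adjacent level pairs (i, i+1) of the angle
#' arccos(<omega_i, omega_i+1> / (|omega_i| |omega_i+1|)), the cosine argument
#' clamped to [-1, 1]. Zero when all levels are collinear with positive sign;
#' bounded by (L-1)*pi. Invariant to positive per-level rescaling and to a
#' global rotation applied to all levels.
#'
#' @param omega L x D latent matrix; no level row may be the zero vector.
#' @return nonnegative scalar.
#' @export
cosinePriorLoss <- function(omega) {
  L <- nrow(omega)
  if (L < 2L) return(0)
  norms <- sqrt(rowSums(omega^2))
  zero <- which(norms == 0)
  if (length(zero))
    stop(sprintf("latent level %d is the zero vector", zero[1L]))
  total <- 0
  for (i in seq_len(L - 1L)) {
    cc <- sum(omega[i, ] * omega[i + 1L, ]) / (norms[i] * norms[i + 1L])
    total <- total + acos(pmin(pmax(cc, -1), 1))
  }
  total
}

# Gradient of the arccos angle sum; the 1/sqrt(1-c^2) factor is floored to
# avoid blowup at exactly (anti)parallel levels.
cosinePriorGrad <- function(omega) {
  L <- nrow(omega)
  g <- omega * 0
  if (L < 2L) return(g)
  norms <- sqrt(rowSums(omega^2))
  for (i in seq_len(L - 1L)) {
    u <- omega[i, ]; v <- omega[i + 1L, ]
    nu <- norms[i]; nv <- norms[i + 1L]
    cc <- pmin(pmax(sum(u * v) / (nu * nv), -1), 1)
    dacos <- -1 / sqrt(max(1 - cc^2, 1e-12))
    g[i, ] <- g[i, ] + dacos * (v / (nu * nv) - cc * u / nu^2)
    g[i + 1L, ] <- g[i + 1L, ] + dacos * (u / (nu * nv) - cc * v / nv^2)
  }
  g
}

#' Papoulis-Gerchberg completion of a masked image
#'
#' Alternating projections between the band-limitation constraint (zero all
#' Fourier coefficients outside the centred passband of
#' `prior@passbandFraction`) and the data-consistency constraint (reset
#' observed cells to their observed values), starting from the observation
#' with masked cells zero. Stops when the max-abs change between successive
#' iterates is at most `prior@pgTol` or after `prior@pgMaxIters` iterations.
#' For observations that are genuinely band-limited within the passband the
#' iteration converges to the exact completion.
#'
#' @param obs a [CorruptedObservation-class] with at least one observed pixel.
#' @param prior a [LatentPrior-class] (only the passband/iteration slots are
#'   used).
#' @return list with `image` (completed matrix, clipped to [0,1]) and `trace`
#'   (a [PGTrace-class]).
#' @export
pgComplete <- function(obs, prior) {
  stopifnot(is(obs, "CorruptedObservation"))
  mask <- obs@mask
  if (!any(mask == 1)) stop("observation has no observed pixels")
  y <- obs@observed
  obsIdx <- mask == 1
  x <- y
  maxIters <- as.integer(prior@pgMaxIters)
  changes <- numeric(maxIters)
  converged <- FALSE
  used <- 0L
  for (it in seq_len(maxIters)) {
    z <- lowpassProject(x, prior@passbandFraction)
    z[obsIdx] <- y[obsIdx]
    changes[it] <- max(abs(z - x))
    x <- z
    used <- it
    if (changes[it] <= prior@pgTol) { converged <- TRUE; break }
  }
  list(image = clip01(x),
       trace = new("PGTrace", iterationsUsed = used,
                   changes = changes[seq_len(used)], converged = converged))
}

#' Intensity prior loss against a Papoulis-Gerchberg completion
#'
#' Sum over masked cells (mask = 0) of (candidate - pgImage)^2; observed
#' cells contribute nothing.
#'
#' @param candidate,pgImage H x W matrices.
#' @param mask H x W binary mask (1 = observed).
#' @return nonnegative scalar.
#' @export
intensityPriorLoss <- function(candidate, pgImage, mask) {
  sameDim(candidate, pgImage, "candidate and PG image")
  checkMask(mask, candidate)
  sum(((candidate - pgImage) * (1 - mask))^2)
}

intensityPriorGrad <- function(candidate, pgImage, mask)
  2 * (candidate - pgImage) * (1 - mask)

#' Combined log-prior
#'
#' The product of prior densities becomes a weighted sum in log domain:
#' returns -(lambdaPrior * meanPriorLoss + lambdaCosine * cosinePriorLoss +
#' lambdaIntensity * intensityPriorLoss). `pgImage`/`mask` may be omitted
#' when `lambdaIntensity` is 0.
#'
#' @param omega L x D latent matrix.
#' @param candidate generated image (only used by the intensity term).
#' @param pgImage Papoulis-Gerchberg completion, or `NULL`.
#' @param mask binary mask, or `NULL`.
#' @param prior a [LatentPrior-class].
#' @param weights a [LossWeights-class].
#' @return scalar log-prior (nonpositive for nonnegative weights).
#' @export
combinedLogPrior <- function(omega, candidate = NULL, pgImage = NULL,
                             mask = NULL, prior, weights) {
  total <- 0
  if (weights@lambdaPrior > 0)
    total <- total + weights@lambdaPrior * meanPriorLoss(omega, prior)
  if (weights@lambdaCosine > 0)
    total <- total + weights@lambdaCosine * cosinePriorLoss(omega)
  if (weights@lambdaIntensity > 0) {
    if (is.null(candidate) || is.null(pgImage) || is.null(mask))
      stop("intensity prior requires candidate, pgImage and mask")
    total <- total +
      weights@lambdaIntensity * intensityPriorLoss(candidate, pgImage, mask)
  }
  -total
}
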