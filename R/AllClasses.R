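#' @import methods
NULL

# Images, masks and latent codes are plain numeric matrices (grayscale, values
# in [0,1]; mask values in {0,1} with 1 = observed; latent codes L x D). The
# structured objects around them are S4 classes with validity checks.

#' Noise parameters of the corruption model
#'
#' Standard deviations of the additive pixel-level Gaussian noise (intensity
#' units on the [0,1] scale) and of the perceptual-noise likelihood term
#' (feature units). Both must be nonnegative; a value of 0 disables the
#' corresponding 1/(2 sigma^2) likelihood scaling.
#'
#' @slot sigmaPixel nonnegative numeric.
#' @slot sigmaPercept nonnegative numeric.
#' @export
setClass("NoiseParams",
  representation(sigmaPixel = "numeric", sigmaPercept = "numeric"),
  prototype(sigmaPixel = 0.05, sigmaPercept = 1),
  validity = function(object) {
    if (length(object@sigmaPixel) != 1L || object@sigmaPixel < 0)
      return("sigmaPixel must be a single nonnegative number")
    if (length(object@sigmaPercept) != 1L || object@sigmaPercept < 0)
      return("sigmaPercept must be a single nonnegative number")
    TRUE
  })

#' @describeIn NoiseParams-class constructor.
#' @param sigmaPixel,sigmaPercept nonnegative standard deviations.
#' @export
NoiseParams <- function(sigmaPixel = 0.05, sigmaPercept = 1)
  new("NoiseParams", sigmaPixel = sigmaPixel, sigmaPercept = sigmaPercept)

#' Mask family specification
#'
#' The benchmark mask families: `chin` (irregular blob in the lower-middle
#' region, ~15% area), `square` (centred square, ~25%), `vrect` (full-height
#' vertical rectangle, ~50%), `bottom` (bottom rows, ~50%), and `freeform`
#' (random brush strokes, any coverage).
#'
#' @slot family character, one of chin/square/vrect/bottom/freeform.
#' @slot targetCoverage fraction of image area to mask, in (0,1).
#' @slot seed integer seed.
#' @export
setClass("MaskSpec",
  representation(family = "character", targetCoverage = "numeric", seed = "numeric"),
  validity = function(object) {
    fams <- c("chin", "square", "vrect", "bottom", "freeform")
    if (length(object@family) != 1L || !(object@family %in% fams))
      return(sprintf("family must be one of %s", paste(fams, collapse = ", ")))
    tc <- object@targetCoverage
    if (length(tc) != 1L || !is.finite(tc) || tc <= 0 || tc >= 1)
      return("targetCoverage must lie in (0,1)")
    TRUE
  })

# Benchmark default coverages per family.
maskFamilyDefaults <- c(chin = 0.15, square = 0.25, vrect = 0.50,
                        bottom = 0.50, freeform = 0.25)

#' @describeIn MaskSpec-class constructor; `targetCoverage` defaults to the
#'   family's benchmark value (chin 0.15, square 0.25, vrect 0.50, bottom 0.50).
#' @param family mask family name.
#' @param targetCoverage fraction in (0,1); `NULL` selects the family default.
#' @param seed integer seed.
#' @export
MaskSpec <- function(family, targetCoverage = NULL, seed = 1L) {
  if (is.null(targetCoverage))
    targetCoverage <- unname(maskFamilyDefaults[family])
  new("MaskSpec", family = family, targetCoverage = targetCoverage, seed = seed)
}

#' Structured prior over the latent code and the band-limited intensity model
#'
#' @slot mu L x D matrix of prior means per latent level.
#' @slot sigma L x D matrix of positive prior standard deviations.
#' @slot passbandFraction fraction of Fourier coefficients in the centred
#'   passband used by the Papoulis-Gerchberg intensity prior, in (0,1].
#' @slot pgMaxIters maximum Papoulis-Gerchberg iterations.
#' @slot pgTol stopping tolerance on the max-abs change between iterates.
#' @slot angularScale reserved scale of the directional distribution over
#'   [0,2*pi]; unused by the default cosine-prior surrogate.
#' @export
setClass("LatentPrior",
  representation(mu = "matrix", sigma = "matrix", passbandFraction = "numeric",
                 pgMaxIters = "numeric", pgTol = "numeric",
                 angularScale = "numeric"),
  validity = function(object) {
    if (!all(dim(object@mu) == dim(object@sigma)))
      return("mu and sigma must have the same L x D shape")
    if (any(object@sigma <= 0)) return("sigma must be positive elementwise")
    pf <- object@passbandFraction
    if (length(pf) != 1L || pf <= 0 || pf > 1)
      return("passbandFraction must lie in (0,1]")
    if (object@pgTol < 0) return("pgTol must be nonnegative")
    if (object@pgMaxIters < 1) return("pgMaxIters must be >= 1")
    if (object@angularScale <= 0) return("angularScale must be positive")
    TRUE
  })

#' @describeIn LatentPrior-class constructor; scalar `mu`/`sigma` are recycled
#'   to the L x D latent shape.
#' @param L,D latent levels and per-level dimension.
#' @param mu,sigma prior mean and standard deviation (scalar or L x D matrix).
#' @param passbandFraction fraction of kept Fourier coefficients, (0,1].
#' @param pgMaxIters,pgTol Papoulis-Gerchberg iteration budget and tolerance.
#' @param angularScale reserved positive scale, default 1.
#' @export
LatentPrior <- function(L = 4L, D = 32L, mu = 0, sigma = 1,
                        passbandFraction = 0.2, pgMaxIters = 500L,
                        pgTol = 1e-7, angularScale = 1) {
  if (!is.matrix(mu)) mu <- matrix(mu, L, D)
  if (!is.matrix(sigma)) sigma <- matrix(sigma, L, D)
  new("LatentPrior", mu = mu, sigma = sigma,
      passbandFraction = passbandFraction, pgMaxIters = pgMaxIters,
      pgTol = pgTol, angularScale = angularScale)
}

#' Loss-term multipliers of the four-term objective
#'
#' Defaults are the minimum-perceptual-error cells of the published
#' hyperparameter ablation grid: pixel 1e-6, perceptual 1e4, cosine 1e-3,
#' prior 1e-3. `lambdaIntensity` defaults to 0 (four-term mode); setting it
#' positive enables the Papoulis-Gerchberg intensity prior as an additive
#' loss ("full prior" mode).
#'
#' @slot lambdaPrior,lambdaCosine,lambdaPixel,lambdaPercept,lambdaIntensity
#'   nonnegative multipliers.
#' @export
setClass("LossWeights",
  representation(lambdaPrior = "numeric", lambdaCosine = "numeric",
                 lambdaPixel = "numeric", lambdaPercept = "numeric",
                 lambdaIntensity = "numeric"),
  validity = function(object) {
    v <- c(object@lambdaPrior, object@lambdaCosine, object@lambdaPixel,
           object@lambdaPercept, object@lambdaIntensity)
    if (length(v) != 5L || any(!is.finite(v)) || any(v < 0))
      return("all loss weights must be single nonnegative numbers")
    TRUE
  })

#' @describeIn LossWeights-class constructor.
#' @param lambdaPrior,lambdaCosine,lambdaPixel,lambdaPercept,lambdaIntensity
#'   nonnegative multipliers.
#' @export
LossWeights <- function(lambdaPrior = 1e-3, lambdaCosine = 1e-3,
                        lambdaPixel = 1e-6, lambdaPercept = 1e4,
                        lambdaIntensity = 0)
  new("LossWeights", lambdaPrior = lambdaPrior, lambdaCosine = lambdaCosine,
      lambdaPixel = lambdaPixel, lambdaPercept = lambdaPercept,
      lambdaIntensity = lambdaIntensity)

#' Forward-measurement configuration
#'
#' `nf = 0` means the measurement is the masked image itself; `nf >= 8`
#' additionally area-averages the masked image down to an nf x nf grid.
#'
#' @slot nf integer measurement side length (0 = no downsampling).
#' @export
setClass("ForwardConfig",
  representation(nf = "numeric"),
  prototype(nf = 0),
  validity = function(object) {
    nf <- object@nf
    if (length(nf) != 1L || nf != round(nf) || nf < 0 || (nf > 0 && nf < 8))
      return("nf must be 0 or an integer >= 8")
    TRUE
  })

#' @describeIn ForwardConfig-class constructor.
#' @param nf measurement side length; 0 disables downsampling.
#' @export
ForwardConfig <- function(nf = 0) new("ForwardConfig", nf = nf)

#' A corrupted observation: masked, noisy image plus its mask and noise model
#'
#' @slot observed H x W matrix; exactly 0 at masked cells, masked-noisy clean
#'   image elsewhere.
#' @slot mask H x W matrix in {0,1}; 1 = observed.
#' @slot noise a [NoiseParams-class] object.
#' @slot seed integer seed that generated the noise.
#' @export
setClass("CorruptedObservation",
  representation(observed = "matrix", mask = "matrix", noise = "NoiseParams",
                 seed = "numeric"),
  validity = function(object) {
    if (!all(dim(object@observed) == dim(object@mask)))
      return("observed and mask shapes differ")
    if (!all(object@mask %in% c(0, 1)))
      return("mask must be binary (1 = observed, 0 = missing)")
    if (any(object@observed[object@mask == 0] != 0))
      return("observed must be exactly 0 at masked cells")
    TRUE
  })

#' Trace of a Papoulis-Gerchberg run
#'
#' @slot iterationsUsed number of iterations performed.
#' @slot changes per-iteration max-abs change between successive iterates.
#' @slot converged whether the final change fell at or below the tolerance.
#' @export
setClass("PGTrace",
  representation(iterationsUsed = "numeric", changes = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (any(!is.finite(object@changes))) return("changes must be finite")
    if (any(object@changes < 0)) return("changes must be nonnegative")
    TRUE
  })

#' Differentiable generator models
#'
#' `GeneratorModel` is the virtual parent of the two reference generators:
#' [LinearGenerator-class], an affine map with a closed-form posterior oracle,
#' and [DecoderGenerator-class], a small trainable upsampling decoder.
#'
#' @slot latentShape integer pair (L, D).
#' @slot imageShape integer pair (H, W).
#' @slot seed integer seed used to create the model.
#' @export
setClass("GeneratorModel",
  representation("VIRTUAL", latentShape = "numeric", imageShape = "numeric",
                 seed = "numeric"))

#' Affine reference generator
#'
#' G(omega) = clip(offset + scale * (A vec(omega) + b)). A and b are drawn
#' from a seeded standard normal scaled by 1/sqrt(L*D); `scale` keeps outputs
#' in the interior of [0,1] so the map is affine on its working range and the
#' affine-Gaussian posterior oracle applies.
#'
#' @slot A (H*W) x (L*D) matrix.
#' @slot b length H*W offset.
#' @slot scale,offset the affine intensity map.
#' @export
setClass("LinearGenerator", contains = "GeneratorModel",
  representation(A = "matrix", b = "numeric", scale = "numeric",
                 offset = "numeric"))

#' Trainable auto-decoder generator
#'
#' latent -> dense -> tanh -> (nearest-upsample 2x -> 3x3 conv -> tanh) ->
#' nearest-upsample 2x -> 3x3 conv -> sigmoid. Trained auto-decoder style
#' (jointly optimized per-image latents) on a phantom corpus; a desk-scale
#' stand-in for a large pretrained generator.
#'
#' @slot params named list of parameter arrays (W1, b1, K2, b2, K3, b3).
#' @slot arch named list of architecture sizes (h0, w0, c0).
#' @slot trainLoss per-epoch mean squared training error.
#' @slot trainLatents matrix of fitted per-image latent rows (training data).
#' @export
setClass("DecoderGenerator", contains = "GeneratorModel",
  representation(params = "list", arch = "list", trainLoss = "numeric",
                 trainLatents = "matrix"))

#' Result of an inpainting run
#'
#' @slot latent L x D latent code of the reported solution.
#' @slot rawGenerated the generator output G(latent).
#' @slot composited mask * observed + (1-mask) * G(latent) (or the raw output
#'   when compositing is disabled).
#' @slot perTermLosses named list of final per-term loss values (unweighted
#'   and weighted).
#' @slot lossTrace total-loss values: initial value, one per iteration, and
#'   the value of the reported solution last.
#' @slot iterations number of optimization iterations run.
#' @slot seed integer seed.
#' @export
setClass("InpaintResult",
  representation(latent = "matrix", rawGenerated = "matrix",
                 composited = "matrix", perTermLosses = "list",
                 lossTrace = "numeric", iterations = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    tr <- object@lossTrace
    if (length(tr) >= 2L && is.finite(tr[1L]) &&
        tr[length(tr)] > tr[1L] + 1e-9)
      return("final loss exceeds initial loss")
    TRUE
  })

#' Per-image Gaussian variational posterior over the latent code
#'
#' @slot mean L x D posterior mean.
#' @slot logStd L x D log standard deviations.
#' @slot fitted whether [bbbFit()] has been run.
#' @slot seed integer seed of the fit.
#' @slot elboTrace per-iteration objective (KL + expected data loss).
#' @export
setClass("VariationalPosterior",
  representation(mean = "matrix", logStd = "matrix", fitted = "logical",
                 seed = "numeric", elboTrace = "numeric"),
  validity = function(object) {
    if (!all(dim(object@mean) == dim(object@logStd)))
      return("mean and logStd shapes differ")
    if (any(!is.finite(object@logStd))) return("logStd must be finite")
    TRUE
  })

# ---- show methods -----------------------------------------------------------

setMethod("show", "NoiseParams", function(object) {
  cat(sprintf("NoiseParams: sigmaPixel=%g, sigmaPercept=%g\n",
              object@sigmaPixel, object@sigmaPercept))
})

setMethod("show", "MaskSpec", function(object) {
  cat(sprintf("MaskSpec: family=%s, targetCoverage=%.3f, seed=%d\n",
              object@family, object@targetCoverage, as.integer(object@seed)))
})

setMethod("show", "LatentPrior", function(object) {
  cat(sprintf(paste0("LatentPrior: L=%d, D=%d, passbandFraction=%.3f, ",
                     "pgMaxIters=%d, pgTol=%g\n"),
              nrow(object@mu), ncol(object@mu), object@passbandFraction,
              as.integer(object@pgMaxIters), object@pgTol))
})

setMethod("show", "LossWeights", function(object) {
  cat(sprintf(paste0("LossWeights: prior=%g, cosine=%g, pixel=%g, ",
                     "percept=%g, intensity=%g\n"),
              object@lambdaPrior, object@lambdaCosine, object@lambdaPixel,
              object@lambdaPercept, object@lambdaIntensity))
})

setMethod("show", "CorruptedObservation", function(object) {
  cat(sprintf(paste0("CorruptedObservation: %dx%d, %.1f%% masked, ",
                     "sigmaPixel=%g, seed=%d\n"),
              nrow(object@observed), ncol(object@observed),
              100 * mean(object@mask == 0), object@noise@sigmaPixel,
              as.integer(object@seed)))
})

setMethod("show", "PGTrace", function(object) {
  cat(sprintf("PGTrace: %d iterations, final change %g, converged=%s\n",
              as.integer(object@iterationsUsed),
              if (length(object@changes)) object@changes[length(object@changes)]
              else NA_real_, object@converged))
})

setMethod("show", "LinearGenerator", function(object) {
  cat(sprintf("LinearGenerator: latent %dx%d -> image %dx%d (seed %d)\n",
              object@latentShape[1L], object@latentShape[2L],
              object@imageShape[1L], object@imageShape[2L],
              as.integer(object@seed)))
})

setMethod("show", "DecoderGenerator", function(object) {
  cat(sprintf(paste0("DecoderGenerator: latent %dx%d -> image %dx%d, ",
                     "%d parameters, final train MSE %.3g\n"),
              object@latentShape[1L], object@latentShape[2L],
              object@imageShape[1L], object@imageShape[2L],
              sum(vapply(object@params, length, 1L)),
              if (length(object@trainLoss))
                object@trainLoss[length(object@trainLoss)] else NA_real_))
})

setMethod("show", "InpaintResult", function(object) {
  cat(sprintf(paste0("InpaintResult: %dx%d image, %d iterations, ",
                     "loss %.4g -> %.4g\n"),
              nrow(object@composited), ncol(object@composited),
              as.integer(object@iterations), object@lossTrace[1L],
              object@lossTrace[length(object@lossTrace)]))
})

setMethod("show", "VariationalPosterior", function(object) {
  cat(sprintf(paste0("VariationalPosterior: %dx%d latent, fitted=%s, ",
                     "mean|std|=%.3g\n"),
              nrow(object@mean), ncol(object@mean), object@fitted,
              mean(exp(object@logStd))))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for package objects
#'
#' @param object a package S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("observedImage", function(object) standardGeneric("observedImage"))
#' @rdname accessors
#' @export
setMethod("observedImage", "CorruptedObservation", function(object) object@observed)

#' @rdname accessors
#' @export
setGeneric("observationMask", function(object) standardGeneric("observationMask"))
#' @rdname accessors
#' @export
setMethod("observationMask", "CorruptedObservation", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("latentShape", function(object) standardGeneric("latentShape"))
#' @rdname accessors
#' @export
setMethod("latentShape", "GeneratorModel", function(object) object@latentShape)

#' @rdname accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))
#' @rdname accessors
#' @export
setMethod("imageShape", "GeneratorModel", function(object) object@imageShape)

#' @rdname accessors
#' @export
setGeneric("compositedImage", function(object) standardGeneric("compositedImage"))
#' @rdname accessors
#' @export
setMethod("compositedImage", "InpaintResult", function(object) object@composited)

#' @rdname accessors
#' @export
setGeneric("latentCode", function(object) standardGeneric("latentCode"))
#' @rdname accessors
#' @export
setMethod("latentCode", "InpaintResult", function(object) object@latent)
#' @rdname accessors
#' @export
setMethod("latentCode", "VariationalPosterior", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "InpaintResult", function(object) object@lossTrace)
#' @rdname accessors
#' @export
setMethod("lossTrace", "VariationalPosterior", function(object) object@elboTrace)

#' @rdname accessors
#' @export
setGeneric("perTermLosses", function(object) standardGeneric("perTermLosses"))
#' @rdname accessors
#' @export
setMethod("perTermLosses", "InpaintResult", function(object) object@perTermLosses)

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "VariationalPosterior", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("posteriorStd", function(object) standardGeneric("posteriorStd"))
#' @rdname accessors
#' @export
setMethod("posteriorStd", "VariationalPosterior", function(object) exp(object@logStd))
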