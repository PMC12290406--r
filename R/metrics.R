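# Quantitative evaluation: RMSE and PSNR on the 0-255 intensity scale, SSIM
# with the standard windowed statistics, the deterministic perceptual proxy,
# masked-region variants, the intra-sample diversity statistic, and the
# one-weight-at-a-time ablation sweep.

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, dynamic range 255, averaged over the valid (unpadded) window
#' positions. Symmetric and bounded by 1 in absolute value; SSIM(x, x) = 1.
#'
#' @param a,b H x W matrices on the [0,1] intensity scale.
#' @return scalar in [-1, 1].
#' @export
ssimIndex <- function(a, b) {
  sameDim(a, b, "SSIM inputs")
  x <- a * 255; y <- b * 255
  w <- gaussianWindow(11L, 1.5)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  mx <- conv2valid(x, w)
  my <- conv2valid(y, w)
  mxx <- conv2valid(x * x, w)
  myy <- conv2valid(y * y, w)
  mxy <- conv2valid(x * y, w)
  vx <- mxx - mx^2
  vy <- myy - my^2
  cxy <- mxy - mx * my
  ssimMap <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(ssimMap)
}

#' Image-quality metrics between a reference and a candidate
#'
#' RMSE on the 0-255 intensity scale; PSNR = 20*log10(255/RMSE), capped at
#' 100 dB for identical images; SSIM ([ssimIndex()]); and the perceptual
#' proxy distance ([perceptualFeatures()] squared distance — labelled
#' `perceptual_proxy`, not a learned metric). With a mask, RMSE and the
#' perceptual proxy are additionally reported over masked (mask = 0) cells
#' only; the masked perceptual proxy compares the images with observed cells
#' zeroed.
#'
#' @param reference,candidate H x W matrices in [0,1].
#' @param mask optional binary mask (1 = observed).
#' @return one-row data.frame (rmse, psnr, ssim, perceptual_proxy, and
#'   rmse_masked / perceptual_proxy_masked when a mask is given).
#' @export
imageMetrics <- function(reference, candidate, mask = NULL) {
  sameDim(reference, candidate, "reference and candidate")
  d <- (reference - candidate) * 255
  rmse <- sqrt(mean(d^2))
  psnr <- if (rmse == 0) 100 else min(20 * log10(255 / rmse), 100)
  rec <- data.frame(
    rmse = rmse, psnr = psnr,
    ssim = ssimIndex(reference, candidate),
    perceptual_proxy = featureDistance(perceptualFeatures(reference),
                                       perceptualFeatures(candidate)))
  if (!is.null(mask)) {
    checkMask(mask, reference)
    holes <- mask == 0
    rec$rmse_masked <- if (any(holes)) sqrt(mean(d[holes]^2)) else 0
    rec$psnr_masked <- if (!any(holes) || rec$rmse_masked == 0) 100
    else min(20 * log10(255 / rec$rmse_masked), 100)
    rec$perceptual_proxy_masked <- featureDistance(
      perceptualFeatures(reference * (1 - mask)),
      perceptualFeatures(candidate * (1 - mask)))
  }
  rec
}

#' Intra-sample perceptual diversity
#'
#' Mean over all unordered pairs of reconstructions of the perceptual-proxy
#' distance. Zero iff all samples are identical in feature space.
#'
#' @param samples list of >= 2 image matrices (or [InpaintResult-class]
#'   objects, whose composited images are used).
#' @return list with `nSamples`, `meanPairwise`, and the symmetric `pairs`
#'   distance matrix.
#' @export
diversityScore <- function(samples) {
  if (length(samples) < 2L) stop("diversity needs at least 2 samples")
  imgs <- lapply(samples, function(s)
    if (is(s, "InpaintResult")) compositedImage(s) else s)
  feats <- lapply(imgs, perceptualFeatures)
  n <- length(imgs)
  pairs <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- featureDistance(feats[[i]], feats[[j]])
    pairs[i, j] <- d
    pairs[j, i] <- d
  }
  list(nSamples = n, meanPairwise = mean(pairs[upper.tri(pairs)]),
       pairs = pairs)
}

#' Published ablation grids for the loss weights
#'
#' The one-column-at-a-time hyperparameter grids: pixel 1e-7..1e-3, percept
#' 1e3..1e7, cosine 1e-4..1, prior 1e-4..1.
#'
#' @param name one of "pixel", "percept", "cosine", "prior".
#' @return numeric grid.
#' @export
ablationGrid <- function(name) {
  switch(name,
         pixel = 10^seq(-7, -3),
         percept = 10^seq(7, 3),
         cosine = 10^seq(-4, 0),
         prior = 10^seq(-4, 0),
         stop("unknown ablation column"))
}

#' One-weight-at-a-time ablation sweep
#'
#' For each value of the swept weight (all other weights held at
#' `baseWeights`), runs MAP inpainting over the corpus and reports the mean
#' masked-region RMSE and mean perceptual proxy, one row per grid point.
#' Deterministic given `seed`.
#'
#' @param suite list of cases, each a list with `clean` (matrix) and `obs`
#'   (a [CorruptedObservation-class]).
#' @param generator a [GeneratorModel-class].
#' @param prior a [LatentPrior-class].
#' @param baseWeights a [LossWeights-class] providing the held-fixed values.
#' @param sweepName which weight to vary ("pixel", "percept", "cosine",
#'   "prior", or "intensity").
#' @param sweepValues grid of values; defaults to [ablationGrid()] for the
#'   published columns.
#' @param fwd a [ForwardConfig-class].
#' @param iterations,lr MAP optimizer settings for each run.
#' @param seed integer seed.
#' @return data.frame with columns weight, value, mean_rmse_masked,
#'   mean_perceptual_proxy.
#' @export
ablationSweep <- function(suite, generator, prior,
                          baseWeights = LossWeights(), sweepName,
                          sweepValues = NULL, fwd = ForwardConfig(),
                          iterations = 200L, lr = 0.01, seed = 1L) {
  if (length(suite) < 1L) stop("empty evaluation corpus")
  if (is.null(sweepValues)) sweepValues <- ablationGrid(sweepName)
  slot <- switch(sweepName, pixel = "lambdaPixel", percept = "lambdaPercept",
                 cosine = "lambdaCosine", prior = "lambdaPrior",
                 intensity = "lambdaIntensity",
                 stop("unknown sweep weight"))
  rows <- lapply(seq_along(sweepValues), function(vi) {
    w <- baseWeights
    methods::slot(w, slot) <- sweepValues[vi]
    recs <- lapply(seq_along(suite), function(i) {
      cs <- suite[[i]]
      res <- mapInpaint(cs$obs, generator, prior, w, fwd,
                        iterations = iterations, lr = lr, seed = seed + i)
      imageMetrics(cs$clean, compositedImage(res), cs$obs@mask)
    })
    recs <- do.call(rbind, recs)
    data.frame(weight = sweepName, value = sweepValues[vi],
               mean_rmse_masked = mean(recs$rmse_masked),
               mean_perceptual_proxy = mean(recs$perceptual_proxy))
  })
  do.call(rbind, rows)
}
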