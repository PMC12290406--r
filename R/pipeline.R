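# End-to-end experiment pipeline: fixtures -> generator -> corruption ->
# MAP/VI inpainting -> evaluation, with a JSON manifest and deterministic
# seeded stages.

#' Build an experiment configuration
#'
#' A validated list describing every stage of [runExperiment()]. All
#' randomness is derived from `seed`; the training/evaluation split mirrors a
#' 90:10 protocol by default (the generator never sees held-out images).
#'
#' @param nTrain,nTest phantom counts for decoder training and held-out
#'   evaluation.
#' @param height,width image size (multiples of 4 for the decoder).
#' @param complexity phantom complexity.
#' @param maskFamily mask family applied to test images (or vector cycled
#'   over them).
#' @param generatorKind "decoder" (trained on the train split) or "linear".
#' @param latentShape integer pair (L, D).
#' @param epochs decoder training epochs.
#' @param noise a [NoiseParams-class].
#' @param prior a [LatentPrior-class], or `NULL` for a standard-normal prior
#'   of the latent shape.
#' @param weights a [LossWeights-class].
#' @param fwd a [ForwardConfig-class].
#' @param mode "map" or "vi".
#' @param iterations,lr inference optimizer settings.
#' @param mcSamples,nSamples variational settings (vi mode).
#' @param warmStart warm-start MAP from the Papoulis-Gerchberg completion.
#' @param initStrategy MAP initialization: "auto" (retrieval init for decoder
#'   generators, seeded prior draw otherwise), "prior", or "nearest".
#' @param seed integer master seed.
#' @param outDir output directory.
#' @return a named list of class "runConfig".
#' @export
runConfig <- function(nTrain = 200L, nTest = 10L, height = 32L, width = 32L,
                      complexity = 3L, maskFamily = "square",
                      generatorKind = c("decoder", "linear"),
                      latentShape = c(4L, 16L), epochs = 40L,
                      noise = NoiseParams(), prior = NULL,
                      weights = LossWeights(), fwd = ForwardConfig(),
                      mode = c("map", "vi"), iterations = 300L, lr = 0.01,
                      mcSamples = 1L, nSamples = 5L, warmStart = FALSE,
                      initStrategy = c("auto", "prior", "nearest"),
                      seed = 1L, outDir = tempfile("bayesinpaint_run_")) {
  generatorKind <- match.arg(generatorKind)
  mode <- match.arg(mode)
  initStrategy <- match.arg(initStrategy)
  if (is.null(prior))
    prior <- LatentPrior(latentShape[1L], latentShape[2L])
  cfg <- list(nTrain = nTrain, nTest = nTest, height = height, width = width,
              complexity = complexity, maskFamily = maskFamily,
              generatorKind = generatorKind, latentShape = latentShape,
              epochs = epochs, noise = noise, prior = prior,
              weights = weights, fwd = fwd, mode = mode,
              iterations = iterations, lr = lr, mcSamples = mcSamples,
              nSamples = nSamples, warmStart = warmStart,
              initStrategy = initStrategy, seed = seed, outDir = outDir)
  class(cfg) <- "runConfig"
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  stripped <- cfg
  stripped$outDir <- NULL
  # version 2 serialization is byte-stable across sessions for these types
  saveRDS(stripped, tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

# Generate the experiment's phantom corpus and held-out corrupted cases.
buildCases <- function(cfg) {
  total <- cfg$nTrain + cfg$nTest
  phantoms <- lapply(seq_len(total), function(i)
    generatePhantom(cfg$height, cfg$width, cfg$complexity,
                    seed = cfg$seed * 10000L + i))
  trainSet <- phantoms[seq_len(cfg$nTrain)]
  testSet <- phantoms[cfg$nTrain + seq_len(cfg$nTest)]
  fams <- rep(cfg$maskFamily, length.out = cfg$nTest)
  cases <- lapply(seq_len(cfg$nTest), function(i) {
    mask <- generateMask(MaskSpec(fams[i], seed = cfg$seed * 100L + i),
                         cfg$height, cfg$width)
    obs <- corruptImage(testSet[[i]], mask, cfg$noise,
                        seed = cfg$seed * 100L + 5000L + i)
    list(clean = testSet[[i]], obs = obs, family = fams[i])
  })
  list(train = trainSet, cases = cases)
}

resolveInit <- function(cfg, generator) {
  if (cfg$initStrategy == "nearest" ||
      (cfg$initStrategy == "auto" && is(generator, "DecoderGenerator")))
    "nearest" else NULL
}

buildGenerator <- function(cfg, trainSet) {
  if (cfg$generatorKind == "linear")
    linearGenerator(cfg$latentShape, c(cfg$height, cfg$width),
                    seed = cfg$seed)
  else
    trainDecoder(trainSet, cfg$latentShape, epochs = cfg$epochs,
                 seed = cfg$seed)
}

#' Run an experiment end to end
#'
#' Executes fixtures -> generator -> corruption -> inference -> evaluation,
#' writes PNGs, a metrics CSV, latent archives and a JSON manifest under
#' `cfg$outDir`, and returns the manifest. Deterministic given the config.
#'
#' @param cfg a [runConfig()] list.
#' @return list manifest (also written to `manifest.json`).
#' @export
runExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  built <- buildCases(cfg)
  generator <- buildGenerator(cfg, built$train)
  genPath <- file.path(cfg$outDir, "generator.rds")
  saveGenerator(generator, genPath)

  metricsRows <- list()
  artifacts <- list(generator = "generator.rds")
  for (i in seq_along(built$cases)) {
    cs <- built$cases[[i]]
    writeImagePNG(cs$clean, file.path(cfg$outDir, sprintf("clean_%03d.png", i)))
    writeMaskPNG(cs$obs@mask, file.path(cfg$outDir, sprintf("mask_%03d.png", i)))
    writeImagePNG(cs$obs@observed,
                  file.path(cfg$outDir, sprintf("corrupt_%03d.png", i)))
    if (cfg$mode == "map") {
      res <- mapInpaint(cs$obs, generator, cfg$prior, cfg$weights, cfg$fwd,
                        iterations = cfg$iterations, lr = cfg$lr,
                        seed = cfg$seed + i, warmStart = cfg$warmStart,
                        init = resolveInit(cfg, generator))
      out <- compositedImage(res)
      writeImagePNG(out, file.path(cfg$outDir, sprintf("inpaint_%03d.png", i)))
      saveRDS(latentCode(res),
              file.path(cfg$outDir, sprintf("latent_%03d.rds", i)))
      rec <- imageMetrics(cs$clean, out, cs$obs@mask)
      rec$image <- i; rec$family <- cs$family
      rec$loss_initial <- lossTrace(res)[1L]
      rec$loss_final <- lossTrace(res)[length(lossTrace(res))]
      metricsRows[[length(metricsRows) + 1L]] <- rec
    } else {
      q <- bbbFit(cs$obs, generator, cfg$prior, cfg$weights, cfg$fwd,
                  iterations = cfg$iterations, lr = cfg$lr,
                  mcSamples = cfg$mcSamples, seed = cfg$seed + i)
      samples <- sampleReconstructions(q, generator, cs$obs,
                                       n = cfg$nSamples,
                                       seed = cfg$seed + 700L + i)
      for (k in seq_along(samples))
        writeImagePNG(compositedImage(samples[[k]]),
                      file.path(cfg$outDir,
                                sprintf("sample_%03d_%02d.png", i, k)))
      saveRDS(list(mean = posteriorMean(q), std = posteriorStd(q)),
              file.path(cfg$outDir, sprintf("posterior_%03d.rds", i)))
      div <- diversityScore(samples)
      for (k in seq_along(samples)) {
        rec <- imageMetrics(cs$clean, compositedImage(samples[[k]]),
                            cs$obs@mask)
        rec$image <- i; rec$family <- cs$family; rec$sample <- k
        rec$diversity_mean_pairwise <- div$meanPairwise
        rec$loss_initial <- lossTrace(q)[1L]
        rec$loss_final <- lossTrace(q)[length(lossTrace(q))]
        metricsRows[[length(metricsRows) + 1L]] <- rec
      }
    }
  }
  metrics <- do.call(rbind, metricsRows)
  metricsPath <- file.path(cfg$outDir, "metrics.csv")
  utils::write.csv(metrics, metricsPath, row.names = FALSE)

  manifest <- list(configHash = configHash(cfg), seed = cfg$seed,
                   mode = cfg$mode, generator = "generator.rds",
                   metrics = "metrics.csv", nTest = cfg$nTest,
                   images = sprintf("clean_%03d.png", seq_len(cfg$nTest)))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(metricsTable = metrics, outDir = cfg$outDir)))
}

#' Compare MAP inpainting against internal baselines
#'
#' For each held-out corrupted image computes the masked-region RMSE of
#' (a) mean-fill (masked cells filled with the mean of observed cells),
#' (b) Papoulis-Gerchberg-only completion, and (c) MAP inpainting, and
#' returns per-image and aggregate tables.
#'
#' @param cfg a [runConfig()] list.
#' @param generator optional pre-built generator (otherwise built from the
#'   config, training the decoder on the train split).
#' @param cases optional pre-built case list from the same config.
#' @return list with `perImage` (data.frame) and `aggregate` (named means).
#' @export
compareBaselines <- function(cfg, generator = NULL, cases = NULL) {
  stopifnot(inherits(cfg, "runConfig"))
  if (is.null(cases)) {
    built <- buildCases(cfg)
    cases <- built$cases
    if (is.null(generator)) generator <- buildGenerator(cfg, built$train)
  } else if (is.null(generator)) {
    stop("cases were supplied without a generator")
  }
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    obs <- cs$obs
    meanFill <- obs@observed
    meanFill[obs@mask == 0] <- mean(obs@observed[obs@mask == 1])
    pg <- pgComplete(obs, cfg$prior)$image
    res <- mapInpaint(obs, generator, cfg$prior, cfg$weights, cfg$fwd,
                      iterations = cfg$iterations, lr = cfg$lr,
                      seed = cfg$seed + i, warmStart = cfg$warmStart,
                      init = resolveInit(cfg, generator))
    rmseMasked <- function(x)
      imageMetrics(cs$clean, x, obs@mask)$rmse_masked
    data.frame(image = i, family = cs$family,
               rmse_meanfill = rmseMasked(meanFill),
               rmse_pg = rmseMasked(pg),
               rmse_map = rmseMasked(compositedImage(res)))
  })
  perImage <- do.call(rbind, rows)
  list(perImage = perImage,
       aggregate = c(meanfill = mean(perImage$rmse_meanfill),
                     pg = mean(perImage$rmse_pg),
                     map = mean(perImage$rmse_map)))
}
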