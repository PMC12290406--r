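# MAP inference: forward operator, pixel and perceptual losses, four-term
# objective, exact gradients, and the closed-form conjugate-model oracle.

test_that("forward operator masks and area-averages", {
  img <- withSeed(1, matrix(runif(256), 16, 16))
  ones <- matrix(1, 16, 16)
  expect_identical(forwardOperator(img, ones, ForwardConfig(0)), img)

  m <- generateMask(MaskSpec("square", seed = 1), 16, 16)
  expect_identical(forwardOperator(img, m, ForwardConfig(16)), m * img)

  ones4 <- matrix(1, 16, 16)
  expect_equal(forwardOperator(ones4, ones4, ForwardConfig(8)),
               matrix(1, 8, 8), tolerance = 1e-12)

  expect_error(forwardOperator(img, m, ForwardConfig(32)), "exceeds")
  # linearity
  a <- withSeed(2, matrix(runif(256), 16, 16))
  expect_equal(forwardOperator(img + 2 * a, m, ForwardConfig(8)),
               forwardOperator(img, m, ForwardConfig(8)) +
                 2 * forwardOperator(a, m, ForwardConfig(8)),
               tolerance = 1e-12)
})

test_that("pixel loss matches its scalar definition", {
  su <- conjugateSetup(seed = 2)
  omega <- su$omTrue
  # generator reproduces the clean image; zero out the observation noise
  obs0 <- corruptImage(su$clean, su$mask, NoiseParams(0, 1), seed = 1)
  obs0@noise@sigmaPixel <- 0
  expect_equal(pixelLoss(omega, obs0, su$gen), 0, tolerance = 1e-20)

  # scalar-loop oracle on the noisy observation
  g <- generatorApply(su$gen, omega)
  sp <- su$obs@noise@sigmaPixel
  acc <- 0
  for (p in seq_along(g))
    acc <- acc + (su$mask[p] * g[p] - su$obs@observed[p])^2
  expect_lt(abs(pixelLoss(omega, su$obs, su$gen) - acc / (2 * sp^2)),
            1e-10 * max(1, acc))
})

test_that("perceptual features are deterministic oriented responses", {
  flat <- matrix(0.5, 32, 32)
  f <- perceptualFeatures(flat)
  expect_equal(max(abs(unlist(f))), 0)

  # a vertical step edge excites the 90-degree channel most
  step <- matrix(0, 32, 32)
  step[, 17:32] <- 1
  fs <- perceptualFeatures(step)
  energies <- vapply(fs[[1]], function(r) sum(r^2), 1)
  expect_equal(names(which.max(energies)), "o90")

  expect_identical(perceptualFeatures(step), fs)
  expect_error(perceptualFeatures(matrix(0.5, 8, 8)), "16x16")
})

test_that("perceptual loss is a symmetric feature distance", {
  a <- generatePhantom(32, 32, 3, seed = 1)
  b <- generatePhantom(32, 32, 3, seed = 2)
  fa <- perceptualFeatures(a)
  fb <- perceptualFeatures(b)
  dab <- BayesInpaint:::featureDistance(fa, fb)
  expect_equal(BayesInpaint:::featureDistance(fb, fa), dab)

  # independent scalar recomputation of the stack distance
  acc <- 0
  for (l in 1:3) for (o in names(fa[[l]]))
    acc <- acc + sum((fa[[l]][[o]] - fb[[l]][[o]])^2)
  expect_lt(abs(dab - acc), 1e-10 * max(1, acc))
  expect_equal(BayesInpaint:::featureDistance(fa, fa), 0)
})

test_that("total loss is additive in its weighted terms", {
  su <- conjugateSetup(seed = 3)
  om <- withSeed(4, matrix(rnorm(16) * 0.5, 2, 8))
  w0 <- LossWeights(0, 0, 0, 0, 0)
  expect_equal(totalLoss(om, su$obs, su$gen, su$prior, w0)$total, 0)

  wp <- LossWeights(0, 0, 2.5, 0, 0)
  expect_equal(totalLoss(om, su$obs, su$gen, su$prior, wp)$total,
               2.5 * pixelLoss(om, su$obs, su$gen), tolerance = 1e-12)

  w <- LossWeights(1e-3, 1e-3, 1e-6, 1e4, 0)
  tl <- totalLoss(om, su$obs, su$gen, su$prior, w)
  recomposed <- 1e-3 * meanPriorLoss(om, su$prior) +
    1e-3 * cosinePriorLoss(om) +
    1e-6 * pixelLoss(om, su$obs, su$gen) +
    1e4 * perceptualLoss(om, su$obs, su$gen)
  expect_lt(abs(tl$total - recomposed), 1e-10 * max(1, recomposed))
  expect_named(tl$terms, c("prior", "cosine", "pixel", "percept", "intensity"))
})

test_that("total-loss gradient matches finite differences", {
  su <- conjugateSetup(seed = 5)
  om <- withSeed(6, matrix(rnorm(16) * 0.5, 2, 8))
  w <- LossWeights(1e-3, 1e-3, 1e-6, 1e4, 0)
  g <- BayesInpaint:::totalLossGrad(om, su$obs, su$gen, su$prior, w)
  h <- 1e-5
  fd <- om * 0
  for (i in seq_along(om)) {
    op <- om; op[i] <- op[i] + h
    on <- om; on[i] <- on[i] - h
    fd[i] <- (totalLoss(op, su$obs, su$gen, su$prior, w)$total -
                totalLoss(on, su$obs, su$gen, su$prior, w)$total) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
})

test_that("MAP on the conjugate model matches the normal-equations oracle", {
  su <- conjugateSetup(seed = 1)
  w <- LossWeights(lambdaPrior = 1, lambdaCosine = 0, lambdaPixel = 1,
                   lambdaPercept = 0)
  vStar <- conjugateMapOracle(su, lambdaPixel = 1, lambdaPrior = 1)
  res <- mapInpaint(su$obs, su$gen, su$prior, w, iterations = 2000L,
                    lr = 0.01, seed = 3)
  vHat <- as.vector(latentCode(res))
  expect_lt(sqrt(sum((vHat - vStar)^2) / sum(vStar^2)), 1e-2)
  # loss decreased
  tr <- lossTrace(res)
  expect_lte(tr[length(tr)], tr[1])
})

test_that("compositing preserves observed pixels exactly", {
  su <- conjugateSetup(seed = 7)
  w <- LossWeights(1e-2, 0, 1, 0, 0)
  res <- mapInpaint(su$obs, su$gen, su$prior, w, iterations = 50L, lr = 0.01,
                    seed = 2)
  comp <- compositedImage(res)
  expect_identical(comp[su$mask == 1], su$obs@observed[su$mask == 1])
  raw <- mapInpaint(su$obs, su$gen, su$prior, w, iterations = 50L, lr = 0.01,
                    seed = 2, composite = FALSE)
  expect_identical(compositedImage(raw), raw@rawGenerated)
})

test_that("MAP defaults follow the published optimization protocol", {
  expect_equal(formals(mapInpaint)$iterations, 500L)
  expect_equal(formals(mapInpaint)$lr, 0.001)
  expect_equal(LossWeights()@lambdaPixel, 1e-6)
  expect_equal(LossWeights()@lambdaPercept, 1e4)
  expect_equal(LossWeights()@lambdaCosine, 1e-3)
  expect_equal(LossWeights()@lambdaPrior, 1e-3)
})
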