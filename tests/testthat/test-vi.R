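# Variational inference: closed-form KL, Bayes-by-Backprop recovery on the
# conjugate model, reparameterization unbiasedness, and posterior sampling.

test_that("diagonal-Gaussian KL matches the coordinate-wise formula", {
  prior <- LatentPrior(3L, 4L, mu = 0.2, sigma = 1.3)
  qSelf <- new("VariationalPosterior", mean = prior@mu,
               logStd = log(prior@sigma), fitted = TRUE, seed = 1,
               elboTrace = numeric(0))
  expect_equal(klDiagGaussian(qSelf, prior), 0, tolerance = 1e-14)

  # 1-D closed form: q = N(0,1), p = N(1,1) -> 1/2
  p1 <- LatentPrior(1L, 1L, mu = 1, sigma = 1)
  q1 <- new("VariationalPosterior", mean = matrix(0, 1, 1),
            logStd = matrix(0, 1, 1), fitted = TRUE, seed = 1,
            elboTrace = numeric(0))
  expect_equal(klDiagGaussian(q1, p1), 0.5, tolerance = 1e-14)

  # seeded parameters vs an independent scalar evaluation
  m <- withSeed(2, matrix(rnorm(12), 3, 4))
  ls <- withSeed(3, matrix(rnorm(12, 0, 0.3), 3, 4))
  q <- new("VariationalPosterior", mean = m, logStd = ls, fitted = TRUE,
           seed = 1, elboTrace = numeric(0))
  acc <- 0
  for (i in 1:3) for (j in 1:4) {
    s <- exp(ls[i, j]); s0 <- prior@sigma[i, j]; mu0 <- prior@mu[i, j]
    acc <- acc + log(s0 / s) + (s^2 + (m[i, j] - mu0)^2) / (2 * s0^2) - 0.5
  }
  expect_equal(klDiagGaussian(q, prior), acc, tolerance = 1e-12)
  expect_gte(klDiagGaussian(q, prior), 0)
})

test_that("with no data terms the posterior collapses onto the prior", {
  su <- conjugateSetup(seed = 4)
  w0 <- LossWeights(0, 0, 0, 0, 0)
  q <- bbbFit(su$obs, su$gen, su$prior, w0, iterations = 800L, lr = 0.02,
              seed = 5)
  expect_lte(klDiagGaussian(q, su$prior), 1e-2)
})

test_that("Bayes-by-Backprop recovers the conjugate Gaussian posterior", {
  su <- conjugateSetup(seed = 1)
  w <- LossWeights(0, 0, 1, 0, 0)
  oracle <- conjugatePosteriorOracle(su, lambdaPixel = 1)
  q <- bbbFit(su$obs, su$gen, su$prior, w, iterations = 3000L, lr = 0.01,
              mcSamples = 4L, seed = 3)
  mHat <- as.vector(posteriorMean(q))
  expect_lt(sqrt(sum((mHat - oracle$mean)^2) / sum(oracle$mean^2)), 0.02)
  vHat <- as.vector(posteriorStd(q))^2
  expect_lt(max(abs(vHat - oracle$var) / oracle$var), 0.20)
  # objective decreased
  tr <- lossTrace(q)
  expect_lt(tr[length(tr)], tr[1])
})

test_that("bbbFit is deterministic given its seed", {
  su <- conjugateSetup(seed = 6)
  w <- LossWeights(0, 0, 1, 0, 0)
  q1 <- bbbFit(su$obs, su$gen, su$prior, w, iterations = 200L, seed = 7)
  q2 <- bbbFit(su$obs, su$gen, su$prior, w, iterations = 200L, seed = 7)
  expect_identical(posteriorMean(q1), posteriorMean(q2))
  expect_identical(posteriorStd(q1), posteriorStd(q2))
})

test_that("reparameterized gradients are unbiased on the linear model", {
  su <- conjugateSetup(seed = 2)
  w <- LossWeights(0, 0, 1, 0, 0)
  m <- su$prior@mu + 0.3
  s <- matrix(0.2, 2, 8)
  # analytic gradient of E[pixel loss] at (m, s): the data term is quadratic
  # with linear gradient, so E[grad(omega)] = grad(m)
  gAnalytic <- BayesInpaint:::totalLossGrad(m, su$obs, su$gen, su$prior, w)
  nDraws <- 10000L
  draws <- withSeed(8, {
    acc <- matrix(0, nDraws, length(m))
    for (k in seq_len(nDraws)) {
      omega <- m + s * matrix(rnorm(length(m)), 2, 8)
      acc[k, ] <- as.vector(
        BayesInpaint:::totalLossGrad(omega, su$obs, su$gen, su$prior, w))
    }
    acc
  })
  mcMean <- colMeans(draws)
  mcSE <- apply(draws, 2, sd) / sqrt(nDraws)
  expect_true(all(abs(mcMean - as.vector(gAnalytic)) <= 3 * mcSE + 1e-9))
})

test_that("posterior samples are diverse yet faithful on observed pixels", {
  su <- conjugateSetup(seed = 9)
  w <- LossWeights(0, 0, 1, 0, 0)
  q <- bbbFit(su$obs, su$gen, su$prior, w, iterations = 1000L, lr = 0.01,
              seed = 10)
  samples <- sampleReconstructions(q, su$gen, su$obs, n = 5L, seed = 11)
  expect_length(samples, 5L)
  lat <- vapply(samples, function(s) as.vector(latentCode(s)), numeric(16))
  expect_equal(nrow(unique(t(lat))), 5L)
  for (s in samples)
    expect_identical(compositedImage(s)[su$mask == 1],
                     su$obs@observed[su$mask == 1])

  again <- sampleReconstructions(q, su$gen, su$obs, n = 5L, seed = 11)
  expect_identical(lapply(again, compositedImage),
                   lapply(samples, compositedImage))
  other <- sampleReconstructions(q, su$gen, su$obs, n = 5L, seed = 12)
  expect_false(identical(compositedImage(other[[1]]),
                         compositedImage(samples[[1]])))

  unfit <- new("VariationalPosterior", mean = q@mean, logStd = q@logStd,
               fitted = FALSE, seed = 1, elboTrace = numeric(0))
  expect_error(sampleReconstructions(unfit, su$gen, su$obs, n = 2L),
               "not been fitted")
})

test_that("a near-degenerate posterior decodes its mean", {
  su <- conjugateSetup(seed = 12)
  q <- new("VariationalPosterior",
           mean = withSeed(13, matrix(rnorm(16) * 0.3, 2, 8)),
           logStd = matrix(-30, 2, 8), fitted = TRUE, seed = 1,
           elboTrace = numeric(0))
  s1 <- sampleReconstructions(q, su$gen, su$obs, n = 1L, seed = 14,
                              composite = FALSE)
  expect_equal(compositedImage(s1[[1]]), generatorApply(su$gen, q@mean),
               tolerance = 1e-9)
})
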