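# Prior terms: mean prior, cosine prior, Papoulis-Gerchberg completion and
# the combined log-prior, each against scalar-loop or linear-algebra oracles.

test_that("mean prior loss matches the standardized quadratic form", {
  prior <- LatentPrior(3L, 4L, mu = 0.3, sigma = 0.7)
  expect_equal(meanPriorLoss(prior@mu, prior), 0)
  expect_equal(meanPriorLoss(prior@mu + prior@sigma, prior), 12)

  om <- withSeed(2, matrix(rnorm(12), 3, 4))
  mu <- withSeed(3, matrix(rnorm(12), 3, 4))
  sg <- withSeed(4, matrix(runif(12, 0.5, 2), 3, 4))
  pr <- new("LatentPrior", mu = mu, sigma = sg, passbandFraction = 0.2,
            pgMaxIters = 10, pgTol = 0, angularScale = 1)
  # independent scalar loop
  acc <- 0
  for (i in 1:3) for (j in 1:4)
    acc <- acc + ((om[i, j] - mu[i, j]) / sg[i, j])^2
  expect_equal(meanPriorLoss(om, pr), acc, tolerance = 1e-12)

  bad <- pr
  bad@sigma[1, 1] <- -1
  expect_error(meanPriorLoss(om, bad), "positive")
})

test_that("cosine prior is the adjacent-level angle sum", {
  om <- matrix(rep(c(1, 2, 3), each = 4), 3, 4, byrow = TRUE)
  expect_equal(cosinePriorLoss(om), 0)

  orth <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(cosinePriorLoss(orth), pi / 2)

  om4 <- withSeed(5, matrix(rnorm(32), 4, 8))
  # independent per-pair scalar oracle
  acc <- 0
  for (i in 1:3) {
    u <- om4[i, ]; v <- om4[i + 1, ]
    acc <- acc + acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  expect_equal(cosinePriorLoss(om4), acc, tolerance = 1e-12)

  # invariant to positive per-level rescaling
  om4s <- om4 * c(2, 0.5, 7, 1)
  expect_equal(cosinePriorLoss(om4s), acc, tolerance = 1e-10)

  # invariant to a global rotation applied to all levels
  R <- qr.Q(qr(withSeed(6, matrix(rnorm(64), 8, 8))))
  expect_equal(cosinePriorLoss(om4 %*% R), acc, tolerance = 1e-10)

  om4z <- om4; om4z[2, ] <- 0
  expect_error(cosinePriorLoss(om4z), "level 2")
})

test_that("cosine prior gradient matches finite differences", {
  om <- withSeed(7, matrix(rnorm(32), 4, 8))
  g <- BayesInpaint:::cosinePriorGrad(om)
  h <- 1e-6
  for (i in c(1, 9, 17, 32)) {
    op <- om; op[i] <- op[i] + h
    on <- om; on[i] <- on[i] - h
    fd <- (cosinePriorLoss(op) - cosinePriorLoss(on)) / (2 * h)
    expect_lt(abs(g[i] - fd), 1e-5 * max(1, abs(fd)))
  }
})

test_that("Papoulis-Gerchberg completion recovers band-limited images", {
  ph <- generateBandlimitedPhantom(32, 32, 0.2, seed = 3)
  mask <- matrix(1, 32, 32)
  mask[withSeed(4, sample(1024, 410))] <- 0  # ~40% missing
  obs <- corruptImage(ph, mask, NoiseParams(0, 1), seed = 1)
  prior <- LatentPrior(passbandFraction = 0.2, pgMaxIters = 500L, pgTol = 0)
  res <- pgComplete(obs, prior)

  # masked cells recovered essentially exactly
  expect_lt(sqrt(mean((res$image - ph)[mask == 0]^2)), 1e-3)

  # agrees with the independent least-squares band-limited solve
  ls <- bandlimitedLeastSquares(obs@observed, mask, 0.2)
  expect_lt(sqrt(mean((res$image - ls)^2)), 1e-2)

  # per-iteration change is non-increasing after the first iteration
  ch <- res$trace@changes
  expect_true(all(diff(ch[-1]) <= 1e-12))
})

test_that("Papoulis-Gerchberg fixes fully observed band-limited inputs", {
  ph <- generateBandlimitedPhantom(32, 32, 0.2, seed = 6)
  obs <- corruptImage(ph, matrix(1, 32, 32), NoiseParams(0, 1), seed = 1)
  prior <- LatentPrior(passbandFraction = 0.2, pgMaxIters = 1L, pgTol = 0)
  res <- pgComplete(obs, prior)
  expect_lt(max(abs(res$image - ph)), 1e-10)

  bad <- corruptImage(ph, matrix(1, 32, 32), NoiseParams(0, 1), seed = 1)
  bad@mask[] <- 0
  bad@observed[] <- 0
  expect_error(pgComplete(bad, prior), "no observed")
})

test_that("intensity prior counts only masked cells", {
  cand <- matrix(0.5, 16, 16)
  expect_equal(intensityPriorLoss(cand, cand, matrix(1, 16, 16)), 0)
  other <- cand + 0.3
  expect_equal(intensityPriorLoss(cand, other, matrix(1, 16, 16)), 0)

  m <- matrix(1, 2, 2); m[2, 1] <- 0
  a <- matrix(0, 2, 2)
  b <- matrix(0, 2, 2); b[2, 1] <- 0.5
  expect_equal(intensityPriorLoss(a, b, m), 0.25)
})

test_that("combined log-prior recomposes its weighted components", {
  om <- withSeed(8, matrix(rnorm(32), 4, 8))
  prior <- LatentPrior(4L, 8L)
  w0 <- LossWeights(0, 0, 0, 0, 0)
  expect_equal(combinedLogPrior(om, prior = prior, weights = w0), 0)

  w <- LossWeights(lambdaPrior = 0.3, lambdaCosine = 0.7, lambdaPixel = 0,
                   lambdaPercept = 0, lambdaIntensity = 0)
  expected <- -(0.3 * meanPriorLoss(om, prior) + 0.7 * cosinePriorLoss(om))
  expect_equal(combinedLogPrior(om, prior = prior, weights = w), expected,
               tolerance = 1e-12)

  w2 <- LossWeights(lambdaPrior = 0.6, lambdaCosine = 1.4, lambdaPixel = 0,
                    lambdaPercept = 0, lambdaIntensity = 0)
  expect_equal(combinedLogPrior(om, prior = prior, weights = w2),
               2 * combinedLogPrior(om, prior = prior, weights = w),
               tolerance = 1e-12)
})
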