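# Image-quality metrics, the diversity statistic, and the ablation sweep.

test_that("identical images score perfectly", {
  img <- generatePhantom(32, 32, 3, seed = 1)
  rec <- imageMetrics(img, img)
  expect_equal(rec$rmse, 0)
  expect_equal(rec$psnr, 100)
  expect_equal(rec$ssim, 1, tolerance = 1e-12)
  expect_equal(rec$perceptual_proxy, 0)
})

test_that("constant offsets give the closed-form RMSE and PSNR", {
  img <- matrix(0.5, 32, 32)
  cand <- img + 10 / 255
  rec <- imageMetrics(img, cand)
  expect_equal(rec$rmse, 10, tolerance = 1e-9)
  expect_equal(rec$psnr, 20 * log10(25.5), tolerance = 1e-9)
})

test_that("SSIM matches a direct windowed-statistics oracle", {
  a <- generatePhantom(24, 24, 3, seed = 2)
  b <- clip01(a + withSeed(3, matrix(rnorm(576, 0, 0.05), 24, 24)))
  got <- ssimIndex(a, b)

  # brute-force loop over valid 11x11 windows
  w <- BayesInpaint:::gaussianWindow(11L, 1.5)
  x <- a * 255; y <- b * 255
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  vals <- c()
  for (i in 1:(24 - 10)) for (j in 1:(24 - 10)) {
    wx <- x[i:(i + 10), j:(j + 10)]
    wy <- y[i:(i + 10), j:(j + 10)]
    mx <- sum(w * wx); my <- sum(w * wy)
    vx <- sum(w * wx^2) - mx^2
    vy <- sum(w * wy^2) - my^2
    cxy <- sum(w * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(got, mean(vals), tolerance = 1e-6)
  expect_equal(ssimIndex(b, a), got, tolerance = 1e-12)
  expect_lte(abs(got), 1)
})

test_that("metrics degrade monotonically with noise", {
  ref <- generatePhantom(32, 32, 3, seed = 4)
  sigmas <- c(0.01, 0.03, 0.06, 0.12)
  recs <- lapply(seq_along(sigmas), function(k)
    imageMetrics(ref, clip01(ref + withSeed(100 + k,
      matrix(rnorm(1024, 0, sigmas[k]), 32, 32)))))
  rmses <- vapply(recs, function(r) r$rmse, 1)
  ssims <- vapply(recs, function(r) r$ssim, 1)
  expect_true(all(diff(rmses) > 0))
  expect_true(all(diff(ssims) < 0))
  # PSNR/RMSE identity on every record
  for (r in recs)
    expect_equal(r$psnr, 20 * log10(255 / r$rmse), tolerance = 1e-9)
})

test_that("masked-region metrics isolate the holes", {
  ref <- generatePhantom(32, 32, 3, seed = 5)
  mask <- generateMask(MaskSpec("square", seed = 6), 32, 32)
  cand <- ref
  cand[mask == 0] <- clip01(cand[mask == 0] + 0.2)
  rec <- imageMetrics(ref, cand, mask)
  expect_gt(rec$rmse_masked, rec$rmse)
  expect_equal(rec$psnr_masked, 20 * log10(255 / rec$rmse_masked),
               tolerance = 1e-9)
  same <- imageMetrics(ref, ref, mask)
  expect_equal(same$rmse_masked, 0)
})

test_that("diversity is the mean pairwise perceptual distance", {
  img <- generatePhantom(32, 32, 3, seed = 7)
  same <- diversityScore(list(img, img, img))
  expect_equal(same$meanPairwise, 0)

  a <- generatePhantom(32, 32, 3, seed = 8)
  b <- generatePhantom(32, 32, 3, seed = 9)
  two <- diversityScore(list(a, b))
  expect_equal(two$meanPairwise,
               BayesInpaint:::featureDistance(perceptualFeatures(a),
                                              perceptualFeatures(b)))

  five <- lapply(10:14, function(s) generatePhantom(32, 32, 3, seed = s))
  d5 <- diversityScore(five)
  acc <- c()
  for (i in 1:4) for (j in (i + 1):5)
    acc <- c(acc, BayesInpaint:::featureDistance(
      perceptualFeatures(five[[i]]), perceptualFeatures(five[[j]])))
  expect_equal(d5$meanPairwise, mean(acc), tolerance = 1e-12)
  expect_true(isSymmetric(d5$pairs))
  expect_error(diversityScore(list(img)), "at least 2")
})

test_that("ablation grids mirror the published sweep and runs are reproducible", {
  expect_equal(ablationGrid("pixel"), 10^seq(-7, -3))
  expect_equal(ablationGrid("percept"), 10^seq(7, 3))
  expect_equal(ablationGrid("cosine"), 10^seq(-4, 0))
  expect_equal(ablationGrid("prior"), 10^seq(-4, 0))

  su <- conjugateSetup(seed = 10)
  suite <- list(list(clean = su$clean, obs = su$obs))
  base <- LossWeights(1e-2, 0, 1, 0, 0)
  tab <- ablationSweep(suite, su$gen, su$prior, base, "pixel",
                       sweepValues = 1, iterations = 60L, lr = 0.02,
                       seed = 2L)
  expect_equal(nrow(tab), 1L)
  # degenerate sweep equals a direct MAP + metrics run
  res <- mapInpaint(su$obs, su$gen, su$prior, base, iterations = 60L,
                    lr = 0.02, seed = 3L)
  direct <- imageMetrics(su$clean, compositedImage(res), su$obs@mask)
  expect_equal(tab$mean_rmse_masked, direct$rmse_masked, tolerance = 1e-12)

  tab2 <- ablationSweep(suite, su$gen, su$prior, base, "pixel",
                        sweepValues = 1, iterations = 60L, lr = 0.02,
                        seed = 2L)
  expect_identical(tab, tab2)
  expect_error(ablationSweep(list(), su$gen, su$prior, base, "pixel"),
               "empty")
})
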