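test_that("block matching recovers identity and exact shifts", {
  v <- smoothVolume(24, seed = 31)
  p <- blockMatchParams(searchRadius = 4L)
  # identical volumes: zero displacement, perfect scores
  corr <- matchBlocks(v, v, p)
  expect_true(all(corr[, c("d1", "d2", "d3")] == 0))
  expect_true(all(abs(corr$score - 1) < 1e-9))
  # moving = fixed shifted by exactly (3, 0, 0) voxels: every interior
  # block reports that displacement (in um)
  a <- voxelData(v)
  mv <- array(0, dim(a)); mv[4:24, , ] <- a[1:21, , ]
  corr2 <- matchBlocks(v, Volume(mv, 1), p)
  interior <- corr2$c1 >= 4 & corr2$c1 <= 16
  expect_true(all(corr2$d1[interior] == 3))
  expect_true(all(corr2$d2[interior] == 0 & corr2$d3[interior] == 0))
})

test_that("featureless volumes are ineligible", {
  flat <- Volume(array(5, c(16, 16, 16)), spacing = 1)
  expect_error(matchBlocks(flat, flat, blockMatchParams()),
               "no textured blocks")
  # constant blocks are excluded even when the floor admits them
  v <- smoothVolume(16, seed = 2)
  a <- voxelData(v); a[1:8, 1:8, 1:8] <- 42  # one flat block
  corr <- matchBlocks(Volume(a, 1), Volume(a, 1),
                      blockMatchParams(varianceFloor = 0))
  expect_false(any(corr$c1 < 8 & corr$c2 < 8 & corr$c3 < 8))
})

test_that("block matching equals the exhaustive brute-force oracle", {
  p <- blockMatchParams(blockSize = 8L, blockStride = 4L,
                        searchRadius = 3L, varianceFloor = 0.5)
  for (seed in 1:8) {
    f <- smoothVolume(16, seed = 300 + seed)
    set.seed(400 + seed)
    m <- Volume(voxelData(f)[c(2:16, 16), , ] +
                  array(rnorm(16^3, sd = 5), rep(16, 3)), 1)
    got <- matchBlocks(f, m, p)
    want <- oracleMatchBlocks(voxelData(f), voxelData(m), 8L, 4L, 3L, 0.5)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$c1, want[, "s1"] + 3.5)
    expect_identical(cbind(got$d1, got$d2, got$d3),
                     unname(want[, c("d1", "d2", "d3")]))
  }
})

test_that("robust fitting recovers generating transforms despite
           outliers", {
  set.seed(50)
  centers <- matrix(runif(300, 0, 100), 100, 3)
  # all displacements equal: pure translation, scale exactly 1
  corr <- data.frame(c1 = centers[, 1], c2 = centers[, 2],
                     c3 = centers[, 3], d1 = 2.5, d2 = 0, d3 = 0,
                     score = 1)
  fit <- robustFit(corr, 0.25)
  expect_equal(scaleFactor(fit$transform), 1, tolerance = 1e-12)
  expect_equal(transformMatrix(fit$transform)[1:3, 4], c(2.5, 0, 0),
               tolerance = 1e-9)
  # displacement field generated by scale 0.9 about the centroid
  ctr <- colMeans(centers)
  disp <- sweep(sweep(centers, 2, ctr), 2, rep(0.9, 3), "*") -
    sweep(centers, 2, ctr)
  corr2 <- data.frame(c1 = centers[, 1], c2 = centers[, 2],
                      c3 = centers[, 3], d1 = disp[, 1], d2 = disp[, 2],
                      d3 = disp[, 3], score = 1)
  fit2 <- robustFit(corr2, 0.25)
  expect_equal(scaleFactor(fit2$transform), 0.9, tolerance = 1e-6)
  # trim 0 on an outlier-free exact field reproduces the closed-form
  # landmark fit exactly
  fit0 <- robustFit(corr2, 0)
  direct <- estimateSimilarity(landmarkSet(centers + disp, centers))
  expect_equal(transformMatrix(fit0$transform),
               transformMatrix(direct$transform), tolerance = 1e-12)
  # 20% gross outliers, trim 0.25: translation still recovered
  corr3 <- corr
  out <- sample(100, 20)
  corr3[out, c("d1", "d2", "d3")] <-
    matrix(runif(60, -30, 30), 20, 3)
  fit3 <- robustFit(corr3, 0.25)
  expect_lt(max(abs(transformMatrix(fit3$transform)[1:3, 4] -
                      c(2.5, 0, 0))), 0.1)
  expect_error(robustFit(corr[1:4, ], 0.25), "fewer than 5")
})

test_that("similarity registration refines a landmark initialisation to
           sub-voxel accuracy", {
  spec <- phantomSpec(dims = c(96L, 96L, 96L), seed = 61,
                      rotationAngle = 5, shrinkageScale = 0.85,
                      translation = c(10, -6, 4), warpAmplitude = 0)
  ph <- generatePhantom(spec)
  binned <- lapply(channels(ph$spim), binVolume, targetSpacing = 1.22)
  fixed <- sumChannels(MultiChannelVolume(binned))
  ct8 <- to8bit(ph$ct)
  # identical inputs with identity init: early convergence at identity
  same <- registerSimilarity(fixed, fixed, similarityTransform(),
                             blockMatchParams(pyramidLevels = 1L))
  expect_true(same$converged)
  expect_equal(transformMatrix(same$transform), diag(4))
  # noisy landmark init refined below 0.5 voxel mean TRE on held-out
  # ground-truth points
  init <- estimateSimilarity(noisyLandmarks(ph$truth$landmarks, 0.4,
                                            seed = 62))$transform
  reg <- registerSimilarity(fixed, ct8, init, blockMatchParams())
  tre <- targetRegistrationError(reg$transform, ph$truth$heldout)
  expect_lt(tre$mean, 0.5 * 1.22)
  # per-iteration residuals are recorded per pyramid level
  expect_true(all(lengths(reg$residuals) >= 1))
  # gross mis-initialisation aborts with a divergence condition rather
  # than returning a silently wrong answer
  bad <- similarityFromComponents(translation = c(500, 500, 500))
  expect_error(registerSimilarity(fixed, ct8, bad, blockMatchParams()),
               class = "voxalignDivergence")
})

test_that("dense refinement is near zero on aligned pairs and damps
           isolated outlier nodes", {
  v <- smoothVolume(32, seed = 70)
  p <- blockMatchParams()
  f <- refineDense(v, v, p)
  nrm <- sqrt(apply(f@vectors^2, 1:3, sum))
  expect_lt(max(nrm), 0.1)  # perfectly aligned: field ~ 0
  expect_equal(spacing(f), 8 * spacing(v))
  # a single outlier node among zeros is suppressed below half its raw
  # magnitude by the Gaussian regularisation
  vec <- array(0, c(5, 5, 5, 3)); vec[3, 3, 3, 1] <- 2
  w <- array(1, c(5, 5, 5))
  sm <- voxalign:::.smoothLattice(vec, w, sigma = 1)
  expect_lt(abs(sm[3, 3, 3, 1]), 1)
  expect_gt(abs(sm[3, 3, 3, 1]), 0)
})

test_that("dense refinement reduces intensity disagreement on a smoothly
           warped pair", {
  spec <- phantomSpec(dims = c(96L, 96L, 96L), seed = 71,
                      warpAmplitude = 4, nWarpComponents = 1L,
                      rotationAngle = 4, shrinkageScale = 0.9,
                      noiseSigmaCt = 0)
  ph <- generatePhantom(spec)
  sceneB <- binVolume(ph$truth$ctScene, factor = 2)
  fixed8 <- to8bit(sceneB, 0, 100)
  ct8 <- to8bit(ph$ct, 0, 100)
  labB <- binVolume(Volume(1.0 * (voxelData(ph$labels) > 0),
                           spacing = spacing(ph$labels)), factor = 2)
  inBody <- voxelData(labB) > 0.99
  init <- estimateSimilarity(ph$truth$landmarks)$transform
  reg <- registerSimilarity(fixed8, ct8, init, blockMatchParams())
  movSim <- resampleVolume(ct8, reg$transform, fixed8, "linear")
  d1 <- mean(abs(voxelData(fixed8)[inBody] - voxelData(movSim)[inBody]))
  field <- refineDense(fixed8, movSim, blockMatchParams())
  movD <- resampleVolume(ct8, composeTransforms(field, reg$transform),
                         fixed8, "linear")
  d2 <- mean(abs(voxelData(fixed8)[inBody] - voxelData(movD)[inBody]))
  expect_lt(d2, d1)
})
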