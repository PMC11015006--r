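test_that("landmark similarity estimation is exact on exact data", {
  set.seed(10)
  X <- matrix(runif(18, 0, 50), 6, 3)
  # identical point sets -> identity
  est <- estimateSimilarity(landmarkSet(X, X))
  expect_equal(est$rmsResidual, 0, tolerance = 1e-10)
  expect_equal(transformMatrix(est$transform), diag(4), tolerance = 1e-9)
  # pure translation: fixed = moving + (5, 0, 0)
  estT <- estimateSimilarity(landmarkSet(sweep(X, 2, c(-5, 0, 0)), X))
  expect_equal(scaleFactor(estT$transform), 1, tolerance = 1e-12)
  expect_equal(transformMatrix(estT$transform)[1:3, 4], c(5, 0, 0),
               tolerance = 1e-9)
  # pure scale 0.8
  estS <- estimateSimilarity(landmarkSet(0.8 * X, X))
  expect_equal(scaleFactor(estS$transform), 0.8, tolerance = 1e-12)
  expect_equal(transformMatrix(estS$transform)[1:3, 1:3], 0.8 * diag(3),
               tolerance = 1e-9)
  expect_equal(transformMatrix(estS$transform)[1:3, 4], c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("similarity recovery is exact for any scale in [0.5, 2] and
           any rotation", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(runif(15, -30, 30), 5, 3)
    s <- runif(1, 0.5, 2)
    R <- rotation3d(rnorm(3), runif(1, 0, 180))
    tr <- similarityFromComponents(s, R, runif(3, -40, 40))
    est <- estimateSimilarity(landmarkSet(applyToPoints(tr, X), X))
    expect_lt(est$rmsResidual, 1e-9)
    expect_equal(scaleFactor(est$transform), s, tolerance = 1e-9)
  }
})

test_that("degenerate landmark inputs are rejected", {
  X <- matrix(runif(12), 4, 3)
  expect_error(estimateSimilarity(landmarkSet(X, X)), "minimum of 5")
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))  # collinear
  expect_error(estimateSimilarity(landmarkSet(line, line)), "collinear")
})

test_that("reflections are corrected to proper rotations", {
  set.seed(4)
  X <- matrix(runif(21, 0, 10), 7, 3)
  Y <- X
  Y[, 1] <- -Y[, 1]  # mirrored targets
  est <- estimateSimilarity(landmarkSet(Y, X))
  A <- transformMatrix(est$transform)[1:3, 1:3]
  expect_gt(det(A), 0)
})

test_that("composition is associative, right-to-left, and merges
           adjacent similarities", {
  t1 <- similarityFromComponents(scale = 2)
  t2 <- similarityFromComponents(translation = c(1, 0, 0))
  # right-to-left: translate first, then scale
  expect_equal(applyToPoints(composeTransforms(t1, t2), matrix(0, 1, 3)),
               matrix(c(2, 0, 0), 1, 3))
  # compose with identity acts exactly as the transform
  set.seed(2)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(applyToPoints(composeTransforms(t1, similarityTransform()),
                             pts),
               applyToPoints(t1, pts))
  # inverse pair cancels
  inv <- composeTransforms(t2, invertSimilarity(t2))
  expect_equal(applyToPoints(inv, pts), pts, tolerance = 1e-12)
  # associativity on random stage lists incl. a displacement field
  set.seed(3)
  f <- displacementField(array(rnorm(2 * 2 * 2 * 3, sd = 0.3),
                               c(2, 2, 2, 3)),
                         nodeSpacing = 10)
  t3 <- similarityFromComponents(0.7, rotation3d(c(1, 0, 0), 30),
                                 c(0, 5, -2))
  ab_c <- composeTransforms(composeTransforms(t3, f), t1)
  a_bc <- composeTransforms(t3, composeTransforms(f, t1))
  expect_equal(applyToPoints(ab_c, pts), applyToPoints(a_bc, pts),
               tolerance = 1e-9)
  # merged similarities equal sequential application
  merged <- composeTransforms(t1, t3)
  expect_equal(length(merged@stages), 1L)
  expect_equal(applyToPoints(merged, pts),
               applyToPoints(t1, applyToPoints(t3, pts)),
               tolerance = 1e-9)
})

test_that("displacement fields interpolate trilinearly and invert by
           fixed point", {
  # single nonzero node: displacement falls off with trilinear weights
  vec <- array(0, c(3, 3, 3, 3))
  vec[2, 2, 2, 1] <- 4
  f <- displacementField(vec, nodeSpacing = 10)
  # at the node itself: full vector
  expect_equal(applyToPoints(f, matrix(c(10, 10, 10), 1, 3)),
               matrix(c(14, 10, 10), 1, 3))
  # halfway to a neighbour along one axis: weight 1/2
  expect_equal(applyToPoints(f, matrix(c(15, 10, 10), 1, 3)),
               matrix(c(17, 10, 10), 1, 3))
  # at the cell centre: weight 1/8
  expect_equal(applyToPoints(f, matrix(c(15, 15, 15), 1, 3)),
               matrix(c(15.5, 15, 15), 1, 3))
  # zero field is the identity
  z <- displacementField(array(0, c(2, 2, 2, 3)), nodeSpacing = 10)
  pts <- matrix(runif(15, 0, 10), 5, 3)
  expect_identical(applyToPoints(z, pts), pts)
  # fixed-point inversion round-trips
  set.seed(6)
  sm <- displacementField(array(rnorm(81, sd = 0.8), c(3, 3, 3, 3)),
                          nodeSpacing = 10)
  fwd <- applyToPoints(sm, pts)
  back <- invertPoints(sm, fwd, tol = 1e-10, maxIter = 100L)
  expect_true(attr(back, "converged"))
  expect_equal(back, pts, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("resampling follows the pull-back convention", {
  # identity on the same grid is the identity (bit-exact for nearest)
  v <- smoothVolume(16, seed = 21)
  out <- resampleVolume(v, similarityTransform(), v, "nearest")
  expect_identical(voxelData(out), voxelData(v))
  # integer translation is an exact shift (linear interp at lattice
  # points is exact)
  tr <- similarityFromComponents(translation = c(3, 0, 0))
  sh <- resampleVolume(v, tr, v, "linear")
  expect_equal(voxelData(sh)[4:16, , ], voxelData(v)[1:13, , ],
               tolerance = 1e-12)
  expect_true(all(voxelData(sh)[1:3, , ] == 0))  # out of domain -> 0
  # oracle equivalence on a 16^3 grid for a general similarity
  t2 <- similarityFromComponents(0.9, rotation3d(c(0, 0, 1), 20),
                                 c(1.5, -2, 0.5), center = rep(7.5, 3))
  got <- resampleVolume(v, t2, v, "linear")
  want <- oracleResampleAffine(voxelData(v), 1, c(0, 0, 0),
                               transformMatrix(t2), c(16L, 16L, 16L), 1,
                               c(0, 0, 0))
  expect_equal(voxelData(got), want, tolerance = 1e-9)
})

test_that("rescaling a ball follows the pull-back convention", {
  # under output(x) = moving(T^{-1}(x)), a moving->fixed scale of 0.5
  # renders a centred ball of radius r at radius r/2 on the reference
  # grid, and scale 2 renders it at radius 2r
  n <- 32
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  r2 <- rowSums((idx - (n - 1) / 2)^2)
  ball <- Volume(array(as.numeric(r2 <= 6^2), c(n, n, n)), spacing = 1)
  ctr <- rep((n - 1) / 2, 3)
  half <- resampleVolume(ball,
                         similarityFromComponents(0.5, center = ctr),
                         ball, "nearest")
  expect_equal(sum(voxelData(half)), 4 / 3 * pi * 3^3, tolerance = 0.1)
  twice <- resampleVolume(ball,
                          similarityFromComponents(2, center = ctr),
                          ball, "nearest")
  expect_equal(sum(voxelData(twice)), 4 / 3 * pi * 12^3, tolerance = 0.1)
})

test_that("transforms round-trip through JSON (+ NRRD fields)", {
  dir <- withr::local_tempdir()
  t1 <- similarityFromComponents(0.85, rotation3d(c(1, 2, 3), 12),
                                 c(4, -5, 6))
  set.seed(8)
  f <- displacementField(array(rnorm(54, sd = 0.5), c(2, 3, 3, 3)),
                         nodeSpacing = 7.5, origin = c(1, 2, 3))
  comp <- composeTransforms(f, t1)
  p <- file.path(dir, "transform.json")
  writeTransform(comp, p)
  back <- readTransform(p)
  pts <- matrix(runif(30, 0, 30), 10, 3)
  expect_equal(applyToPoints(back, pts), applyToPoints(comp, pts),
               tolerance = 1e-6)
  expect_equal(back@stages[[2]]@matrix, t1@matrix, tolerance = 1e-12)
})
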