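test_that("Otsu threshold maximises between-class variance with
           deterministic ties", {
  # two point masses at 0 and 255: every separating cut ties, the lowest
  # wins, so the threshold sits at the upper edge of the first bin
  vals <- c(rep(0, 50), rep(255, 50))
  thr <- otsuThreshold(vals)
  expect_equal(thr, 255 / 256)
  expect_equal(thr, oracleOtsu(vals))
  expect_identical(sum(vals > thr), 50L)
  # two well-separated Gaussian modes: the threshold lands in the gap.
  # With an empty gap every separating cut ties on between-class
  # variance, so the lowest-cut rule places it just above the lower
  # mode's support
  set.seed(80)
  g <- c(rnorm(5e4, 50, 10), rnorm(5e4, 200, 10))
  t2 <- otsuThreshold(g)
  expect_gt(t2, 50 + 3 * 10); expect_lt(t2, 150)
  expect_equal(t2, oracleOtsu(g))
  expect_identical(sum(g > t2), 50000L)  # splits the modes exactly
  # constant input is a degenerate histogram
  expect_error(otsuThreshold(rep(3, 10)), "degenerate")
})

test_that("Otsu equals the exhaustive oracle on seeded random
           histograms", {
  for (seed in 1:25) {
    set.seed(500 + seed)
    n <- sample(200:2000, 1)
    vals <- switch(1 + seed %% 3,
                   rnorm(n, 100, 30),
                   c(rnorm(n, 60, 15), rnorm(n, 180, 25)),
                   runif(n, 0, 1000))
    expect_equal(otsuThreshold(vals), oracleOtsu(vals))
  }
})

test_that("marker fractions count exactly within combined labels", {
  # constructed bimodal tissue: exactly 250 of 1000 voxels above the cut
  set.seed(81)
  lab <- array(0L, c(10, 10, 20))
  lab[, , 1:10] <- 1L  # tissue of 1000 voxels
  ch <- array(0, c(10, 10, 20))
  bright <- sample(which(lab == 1L), 250)
  ch[bright] <- 200 + rnorm(250, 0, 5)
  ch[setdiff(which(lab == 1L), bright)] <- 10 + rnorm(750, 0, 5)
  labels <- labelVolume(lab, c(retina = 1L), spacing = 1.22)
  q <- markerFraction(Volume(ch, 1.22), labels, combineIds = 1L,
                      tissueId = 1L, channelName = "chanA")
  expect_equal(q$fraction, 0.25)
  expect_identical(q$marker_voxels, 250L)
  expect_equal(q$volume_um3, 1000 * 1.22^3)
  # voxels outside the combined labels must not leak into the histogram:
  # a channel constant inside the region errors in Otsu even if bright
  # structure exists outside
  ch2 <- array(0, c(10, 10, 20))
  ch2[, , 15:20] <- 500  # bright, but outside the label region
  expect_error(markerFraction(Volume(ch2, 1.22), labels, 1L, 1L),
               "degenerate")
  # grid mismatch and empty tissue are errors
  expect_error(markerFraction(Volume(ch, 2.44), labels, 1L, 1L), "grid")
  expect_error(markerFraction(Volume(ch, 1.22), labels, c(1L, 2L), 2L),
               "empty tissue")
  expect_error(markerFraction(Volume(ch, 1.22), labels, 1L, 2L),
               "combineIds")
})

test_that("marker fractions are invariant under affine intensity
           rescaling and conserve mask voxels", {
  spec <- phantomSpec(dims = c(64L, 64L, 64L), seed = 82,
                      warpAmplitude = 0, nNuclei = 150L)
  ph <- generatePhantom(spec)
  labels <- ph$labels
  ids <- unname(labelTable(labels)[c("retina", "brain")])
  for (ch in channels(ph$spim)[c("chanA", "chanC")]) {
    qr <- markerFraction(ch, labels, ids, ids[1])
    qb <- markerFraction(ch, labels, ids, ids[2])
    # brute-force counting oracle
    thr <- oracleOtsu(voxelData(ch)[voxelData(labels) %in% ids])
    expect_equal(qr$threshold, thr)
    expect_identical(qr$marker_voxels,
                     sum(voxelData(ch) > thr & voxelData(labels) == ids[1]))
    expect_identical(qb$marker_voxels,
                     sum(voxelData(ch) > thr & voxelData(labels) == ids[2]))
    # conservation: per-tissue counts never exceed the combined mask
    total <- sum(voxelData(ch) > thr & voxelData(labels) %in% ids)
    expect_lte(qr$marker_voxels + qb$marker_voxels, total)
    expect_identical(qr$marker_voxels + qb$marker_voxels, total)
    # monotone rescale x -> 2x + 7 leaves the fractions unchanged
    ch2 <- Volume(2 * voxelData(ch) + 7, spacing = spacing(ch),
                  origin = origin(ch))
    expect_equal(markerFraction(ch2, labels, ids, ids[1])$fraction,
                 qr$fraction)
  }
})

test_that("tissue volumes are exact voxel counts times spacing cubed", {
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 2L
  lv <- labelVolume(lab, c(brain = 2L), spacing = 1.22)
  tv <- tissueVolumes(lv)
  expect_identical(tv$voxels, 1L)
  expect_equal(tv$volume_um3, 1.815848, tolerance = 1e-6)
  # empty label volume -> empty table
  empty <- labelVolume(array(0L, c(3, 3, 3)), c(brain = 2L), 1)
  expect_identical(nrow(tissueVolumes(empty)), 0L)
  # ball of radius 10 voxels: count matches brute-force enumeration
  n <- 24
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  inside <- rowSums((idx - (n - 1) / 2)^2) <= 100
  ball <- labelVolume(array(as.integer(inside), c(n, n, n)),
                      c(lens = 1L), spacing = 0.5)
  expect_identical(tissueVolumes(ball)$voxels, sum(inside))
})

test_that("shrinkage follows the linear scale convention", {
  expect_identical(shrinkagePercent(similarityTransform()), 0)
  # tomography-relative scale 0.795 corresponds to 20.5% shrinkage
  expect_equal(shrinkagePercent(similarityFromComponents(1 / 0.795)), 20.5,
               tolerance = 1e-9)
  # scaling twice by s' composes to 1 - s'^2
  s <- 0.9
  tw <- composeTransforms(similarityFromComponents(1 / s),
                          similarityFromComponents(1 / s))
  expect_equal(shrinkagePercent(tw@stages[[1]]), (1 - s^2) * 100,
               tolerance = 1e-9)
})

test_that("group comparison collates records without inventing
           statistics", {
  q1 <- data.frame(tissue = "retina", channel = "chanA", threshold = 10,
                   marker_voxels = 5L, tissue_voxels = 50L,
                   fraction = 0.1, volume_um3 = 90.8)
  one <- compareGroups(list(q1), "wildtype")
  expect_identical(nrow(one$table), 1L)
  expect_identical(one$table$group, "wildtype")
  q2 <- q1; q2$fraction <- 0.3
  q3 <- q1; q3$fraction <- 0.5
  out <- compareGroups(list(q1, q2, q3),
                       c("wildtype", "incomplete", "complete"))
  expect_identical(nrow(out$table), 3L)
  expect_equal(sum(out$table$fraction), 0.1 + 0.3 + 0.5)
  expect_identical(nrow(out$plotData), 6L)  # fraction + volume per record
  expect_error(compareGroups(list(q1, q2), "wildtype"), "one grouping")
})
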