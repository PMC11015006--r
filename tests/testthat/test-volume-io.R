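test_that("volumes round-trip through TIFF and NRRD bit-exactly", {
  dir <- withr::local_tempdir()
  v8 <- Volume(array(sample(0:255, 24, replace = TRUE), c(2, 3, 4)),
               spacing = 1.22, origin = c(1, 2, 3), dtypeTag = "uint8")
  v16 <- Volume(array(sample(0:65535, 60, replace = TRUE), c(3, 4, 5)),
                spacing = 0.406, dtypeTag = "uint16")
  vf <- Volume(array(c(-1.5, 0.25, 1e6, seq_len(24 - 3) / 2), c(2, 3, 4)),
               spacing = 1.22, dtypeTag = "float32")

  p8 <- file.path(dir, "v8.tif")
  writeVolume(v8, p8)
  r8 <- readVolume(p8)
  expect_identical(voxelData(r8), voxelData(v8))
  expect_equal(spacing(r8), 1.22, tolerance = 1e-6)
  expect_equal(origin(r8), c(1, 2, 3), tolerance = 1e-6)
  expect_identical(dtypeTag(r8), "uint8")

  p16 <- file.path(dir, "v16.tif")
  writeVolume(v16, p16)
  expect_identical(voxelData(readVolume(p16)), voxelData(v16))

  pf <- file.path(dir, "vf.nrrd")
  writeVolume(vf, pf)
  rf <- readVolume(pf)
  expect_identical(voxelData(rf), voxelData(vf))  # float32-representable
  expect_equal(spacing(rf), 1.22, tolerance = 1e-6)

  # ascii NRRD (the plain-text fixture encoding)
  pa <- file.path(dir, "va.nrrd")
  writeVolume(v8, pa, format = "nrrd", encoding = "ascii")
  expect_identical(voxelData(readVolume(pa)), voxelData(v8))

  # float32 cannot go to TIFF
  expect_error(writeVolume(vf, file.path(dir, "bad.tif")), "float32")
})

test_that("TIFF stack shape passes through and spacing is never assumed", {
  dir <- withr::local_tempdir()
  pages <- lapply(1:3, function(i) matrix(runif(20), 4, 5))
  p <- file.path(dir, "stack.tif")
  tiff::writeTIFF(pages, p, bits.per.sample = 16L)
  expect_error(readVolume(p), "spacing")
  v <- readVolume(p, spacing = 1.22)
  expect_identical(dim(voxelData(v)), c(3L, 4L, 5L))
})

test_that("anisotropic NRRD spacing is rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "aniso.nrrd")
  con <- file(p, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "spacings: 1.0 1.0 2.0", "encoding: ascii", ""), con)
  writeLines(paste(0:7, collapse = " "), con)
  close(con)
  expect_error(readVolume(p), "isotropic")
})

test_that("crop copies values, shifts the origin, and composes", {
  cube <- depthMajorCube(spacing = 1.22)
  expect_identical(voxelData(cropVolume(cube, c(0, 0, 0), c(2, 2, 2))),
                   voxelData(cube))
  one <- cropVolume(cube, c(0, 0, 0), c(1, 1, 1))
  expect_identical(as.vector(voxelData(one)), 0)
  expect_identical(origin(one), origin(cube))
  # depth-slab crop: keeps values 4..7 and shifts origin z by one spacing
  slab <- cropVolume(cube, c(1, 0, 0), c(2, 2, 2))
  expect_identical(dim(voxelData(slab)), c(1L, 2L, 2L))
  expect_identical(sort(as.vector(voxelData(slab))), c(4, 5, 6, 7))
  expect_equal(origin(slab), c(1.22, 0, 0))
  expect_error(cropVolume(cube, c(0, 0, 0), c(0, 2, 2)), "range")
  expect_error(cropVolume(cube, c(0, 0, 0), c(3, 2, 2)), "range")
  # crop-of-crop equals single crop with the composed box
  v <- smoothVolume(12, seed = 5)
  a <- cropVolume(cropVolume(v, c(2, 1, 0), c(10, 11, 12)),
                  c(1, 2, 3), c(6, 7, 8))
  b <- cropVolume(v, c(3, 3, 3), c(8, 8, 8))
  expect_identical(voxelData(a), voxelData(b))
  expect_identical(origin(a), origin(b))
})

test_that("binning is a block mean that preserves the retained mean", {
  cube <- depthMajorCube()
  expect_identical(voxelData(binVolume(cube, factor = 1)), voxelData(cube))
  b <- binVolume(cube, factor = 2)
  expect_equal(as.vector(voxelData(b)), 3.5)
  expect_equal(origin(b), c(0.5, 0.5, 0.5))
  # the pipeline's factor: 0.406 um fluorescence to 1.22 um tomography
  v <- Volume(array(runif(27), c(3, 3, 3)), spacing = 0.406)
  expect_equal(round(1.22 / 0.406), 3)
  b3 <- binVolume(v, targetSpacing = 1.22)
  expect_equal(spacing(b3), 0.406 * 3)
  expect_equal(as.vector(voxelData(b3)), mean(voxelData(v)), tolerance = 1e-6)
  # trailing partial blocks are dropped; retained-region mean preserved
  w <- smoothVolume(11, seed = 9)
  bw <- binVolume(w, factor = 2)
  expect_identical(dim(voxelData(bw)), c(5L, 5L, 5L))
  expect_equal(mean(voxelData(bw)),
               mean(voxelData(w)[1:10, 1:10, 1:10]), tolerance = 1e-6)
  expect_error(binVolume(w, factor = 12), "extent")
  expect_error(binVolume(w, targetSpacing = 0.1), "finer")
})

test_that("8-bit conversion is linear with clipping, half-up, monotone", {
  ramp <- Volume(array(0:1000, c(7, 11, 13)), spacing = 1)
  r <- to8bit(ramp, 0, 100)
  expect_identical(dtypeTag(r), "uint8")
  expect_equal(voxelData(r)[voxelData(ramp) == 500], 128)  # round half-up
  expect_equal(range(voxelData(r)), c(0, 255))
  # monotonicity over the whole ramp
  o <- voxelData(r)[order(voxelData(ramp))]
  expect_true(all(diff(o) >= 0))
  # constant input -> all zero
  const <- Volume(array(7, c(2, 2, 2)), spacing = 1)
  expect_true(all(voxelData(to8bit(const)) == 0))
  # two-valued input maps to the endpoints
  tv <- Volume(array(rep(c(10, 20), 8), c(4, 2, 2)), spacing = 1)
  expect_identical(sort(unique(as.vector(voxelData(to8bit(tv, 0, 100))))),
                   c(0, 255))
  # percentile clipping: a single hot voxel cannot flatten the contrast
  hot <- smoothVolume(8, seed = 1)
  hv <- voxelData(hot); hv[1] <- 1e7
  h8 <- to8bit(Volume(hv, spacing = 1))
  expect_gt(stats::sd(voxelData(h8)[-1]), 10)
  expect_error(to8bit(ramp, 50, 50), "pLo")
})

test_that("channel summation is voxelwise and preserves local maxima", {
  base <- array(0, c(8, 8, 8))
  a <- base; a[3, 3, 3] <- 100
  b <- base; b[6, 6, 6] <- 80
  mc <- MultiChannelVolume(list(Volume(a, 1), Volume(b, 1)))
  s <- sumChannels(mc)
  expect_identical(dtypeTag(s), "uint8")
  sd <- voxelData(s)
  expect_equal(which(sd == max(sd)),
               which(as.vector(a) == 100))  # channel A spike survives
  expect_gt(sd[6, 6, 6], 0.7 * 255 * 0.8)   # channel B spike survives
  # one channel: just the 8-bit rescale of itself
  one <- sumChannels(MultiChannelVolume(list(Volume(a, 1))))
  expect_identical(voxelData(one), voxelData(to8bit(Volume(a, 1), 0, 100)))
  # two identical channels: same spatial pattern as one
  twice <- sumChannels(MultiChannelVolume(list(Volume(a, 1), Volume(a, 1))))
  expect_identical(voxelData(twice), voxelData(one))
  # geometric mismatch is an error
  expect_error(MultiChannelVolume(list(Volume(a, 1), Volume(b, 2))),
               "share")
})
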