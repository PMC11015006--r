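#' Default ellipsoidal tissue layout for a phantom
#'
#' Four nested ellipsoids -- body, retina, brain, lens -- scaled to the
#' grid extent, echoing the organ layout of a small fish embryo. Later
#' entries override earlier ones in the label volume (the lens sits
#' inside the retina region).
#'
#' @param extent world extent (um, 3-vector) of the fluorescence grid.
#' @return list of \code{list(label, name, center, semiaxes)} entries.
#' @export
defaultTissues <- function(extent) {
  list(
    list(label = 4L, name = "body",
         center = extent * 0.5, semiaxes = extent * 0.42),
    list(label = 1L, name = "retina",
         center = extent * c(0.50, 0.62, 0.40),
         semiaxes = extent * c(0.15, 0.13, 0.13)),
    list(label = 2L, name = "brain",
         center = extent * c(0.50, 0.38, 0.50),
         semiaxes = extent * c(0.18, 0.15, 0.16)),
    list(label = 3L, name = "lens",
         center = extent * c(0.50, 0.70, 0.30),
         semiaxes = extent * 0.06)
  )
}

#' Construct a PhantomSpec
#'
#' Defaults model the study conditions of the correlative pipeline: a
#' fine fluorescence grid (0.406 um voxels) and a 3x coarser tomography
#' grid (1.22 um), sparse marker channels versus a dense histology-like
#' rendering, a similarity transform whose scale component models the
#' 20.5 percent mean linear shrinkage of dehydrated stained specimens
#' (scale 0.795), a band-limited residual warp mimicking smooth local
#' bulging, and additive Gaussian noise at SNR 10 relative to the
#' nucleus peak intensity of 100.
#'
#' @inheritParams PhantomSpec-class
#' @param dims fluorescence grid extents (default 128^3).
#' @param tissues tissue ellipsoids; default [defaultTissues()].
#' @param markerMaps per-channel expression maps; the default has one
#'   retina-specific, one brain-specific and one shared channel.
#' @param seed integer seed; fully determines all phantom outputs.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dims = c(128L, 128L, 128L), spimSpacing = 0.406,
                        ctSpacing = 1.22, nNuclei = 400L,
                        nucleusRadius = 1.8, tissues = NULL,
                        markerMaps = NULL, shrinkageScale = 0.795,
                        rotationAxis = c(0, 0, 1), rotationAngle = 5,
                        translation = c(0, 0, 0), warpAmplitude = 3,
                        nWarpComponents = 2L, noiseSigmaSpim = 10,
                        noiseSigmaCt = 10, seed = 1L) {
  dims <- as.integer(dims)
  extent <- dims * spimSpacing
  if (is.null(tissues)) tissues <- defaultTissues(extent)
  if (is.null(markerMaps)) {
    allIds <- vapply(tissues, `[[`, integer(1), "label")
    markerMaps <- list(
      # nuclear counterstain imaged alongside the markers: expressed by
      # every nucleus, it gives the summed volume the structural content
      # that makes cross-modal block matching possible
      list(name = "nuc", tissues = allIds, prob = 1.0),
      list(name = "chanA", tissues = 1L, prob = 0.8),
      list(name = "chanB", tissues = 2L, prob = 0.8),
      list(name = "chanC", tissues = c(1L, 2L), prob = 0.5)
    )
  }
  for (tis in tissues) {
    if (any(tis$center - tis$semiaxes < 0) ||
        any(tis$center + tis$semiaxes > extent)) {
      stop("tissue '", tis$name, "' exceeds the grid")
    }
  }
  new("PhantomSpec", dims = dims, spimSpacing = spimSpacing,
      ctSpacing = ctSpacing, nNuclei = as.integer(nNuclei),
      nucleusRadius = nucleusRadius, tissues = tissues,
      markerMaps = markerMaps, shrinkageScale = shrinkageScale,
      rotationAxis = as.double(rotationAxis),
      rotationAngle = as.double(rotationAngle),
      translation = as.double(translation),
      warpAmplitude = as.double(warpAmplitude),
      nWarpComponents = as.integer(nWarpComponents),
      noiseSigmaSpim = noiseSigmaSpim, noiseSigmaCt = noiseSigmaCt,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d x %d x %d @ %.3f um, CT @ %.2f um, ",
                     "%d nuclei, shrinkage scale %.3f, seed %d\n"),
              object@dims[1], object@dims[2], object@dims[3],
              object@spimSpacing, object@ctSpacing, object@nNuclei,
              object@shrinkageScale, object@seed))
})

## squared normalized ellipsoid coordinate q(x) over a whole grid:
## q <= 1 inside. Returns a 3D array.
.ellipsoidQ <- function(dims, spacing, org, center, semi) {
  ax <- lapply(1:3, function(a) {
    x <- org[a] + spacing * (seq_len(dims[a]) - 1L)
    ((x - center[a]) / semi[a])^2
  })
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
}

## additive Gaussian splats at world centers (um) into a 3D array
.splat <- function(arr, dims, spacing, org, centers, amp, sigma) {
  r <- 3 * sigma
  for (n in seq_len(nrow(centers))) {
    cidx <- (centers[n, ] - org) / spacing  # continuous 0-based index
    lo <- pmax(floor(cidx - r / spacing), 0)
    hi <- pmin(ceiling(cidx + r / spacing), dims - 1)
    if (any(lo > hi)) next
    ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
    g1 <- exp(-((ii - cidx[1]) * spacing)^2 / (2 * sigma^2))
    g2 <- exp(-((jj - cidx[2]) * spacing)^2 / (2 * sigma^2))
    g3 <- exp(-((kk - cidx[3]) * spacing)^2 / (2 * sigma^2))
    blob <- amp * outer(outer(g1, g2), g3)
    arr[ii + 1, jj + 1, kk + 1] <- arr[ii + 1, jj + 1, kk + 1] + blob
  }
  arr
}

#' Generate a paired multimodal phantom with known ground truth
#'
#' Places nuclei as Gaussian blobs inside ellipsoidal tissues, renders
#' (i) sparse fluorescence channels showing only marker-expressing
#' nuclei on the fine fixed grid, and (ii) a dense histology-like
#' volume showing all nuclei plus tissue-boundary shells, warped by the
#' true residual field, transformed by the inverse of the true
#' similarity (so the returned tomography volume is related to the
#' fluorescence volume by exactly that similarity-plus-warp, including
#' the shrinkage scale), resampled to the coarse tomography grid and
#' corrupted with Gaussian noise. The label volume lives on the fixed
#' grid. At least 5 paired landmarks (tissue centroids plus interior
#' points) are returned in both spaces, along with a held-out landmark
#' set for target-registration-error evaluation.
#'
#' All randomness is drawn from one stream seeded by \code{spec@seed};
#' the global random state is restored on exit, and rerunning with the
#' same spec is bit-identical.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{spim} ([MultiChannelVolume-class]),
#'   \code{ct} ([Volume-class]), \code{labels} ([LabelVolume-class]) and
#'   \code{truth}: a list holding \code{transform} (the true
#'   [SimilarityTransform-class], moving CT to fixed), \code{warp} (the
#'   true [DisplacementField-class] or NULL), \code{composite} (their
#'   composition), \code{landmarks} and \code{heldout}
#'   ([LandmarkSet-class]s), \code{nuclei} (data frame of positions,
#'   tissue labels and per-channel expression), \code{ctScene} (the
#'   noise-free tomography-contrast rendering on the fixed grid) and
#'   \code{shrinkagePercent}.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", oldSeed, envir = globalenv())
    }
  })
  set.seed(spec@seed)

  dims <- spec@dims
  sp <- spec@spimSpacing
  org <- c(0, 0, 0)
  extent <- dims * sp
  sigma <- spec@nucleusRadius / 2
  amp <- 100
  tissues <- spec@tissues

  ## ---- nuclei -----------------------------------------------------------
  tvol <- vapply(tissues, function(t) prod(t$semiaxes), numeric(1))
  draw <- sample(seq_along(tissues), spec@nNuclei, replace = TRUE,
                 prob = tvol)
  pos <- matrix(0, spec@nNuclei, 3)
  for (n in seq_len(spec@nNuclei)) {
    tis <- tissues[[draw[n]]]
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    pos[n, ] <- tis$center + tis$semiaxes * u * 0.97
  }
  ## resolved tissue label = last ellipsoid containing the nucleus
  nucLabel <- integer(spec@nNuclei)
  for (tis in tissues) {
    q <- rowSums(sweep(sweep(pos, 2, tis$center), 2, tis$semiaxes, "/")^2)
    nucLabel[q <= 1] <- tis$label
  }

  ## ---- label volume (fixed grid) ---------------------------------------
  lab <- array(0L, dims)
  qList <- vector("list", length(tissues))
  for (i in seq_along(tissues)) {
    tis <- tissues[[i]]
    q <- .ellipsoidQ(dims, sp, org, tis$center, tis$semiaxes)
    qList[[i]] <- q
    lab[q <= 1] <- tis$label
  }
  tab <- vapply(tissues, `[[`, integer(1), "label")
  names(tab) <- vapply(tissues, `[[`, character(1), "name")
  labels <- labelVolume(lab, tab, spacing = sp, origin = org)

  ## ---- fluorescence channels (sparse) ----------------------------------
  chans <- list()
  exprMat <- matrix(FALSE, spec@nNuclei, length(spec@markerMaps))
  for (m in seq_along(spec@markerMaps)) {
    mm <- spec@markerMaps[[m]]
    expressing <- nucLabel %in% mm$tissues &
      stats::runif(spec@nNuclei) < mm$prob
    exprMat[, m] <- expressing
    img <- array(0, dims)
    if (any(expressing)) {
      img <- .splat(img, dims, sp, org,
                    pos[expressing, , drop = FALSE], amp, sigma)
    }
    if (spec@noiseSigmaSpim > 0) {
      img <- img + stats::rnorm(length(img), 0, spec@noiseSigmaSpim)
    }
    img <- pmax(round(img), 0)
    chans[[m]] <- Volume(array(img, dims), spacing = sp, origin = org,
                         dtypeTag = "uint16")
  }
  spim <- MultiChannelVolume(chans,
                             vapply(spec@markerMaps, `[[`,
                                    character(1), "name"))

  ## ---- tomography-contrast scene on the fixed grid ---------------------
  scene <- array(0, dims)
  scene <- .splat(scene, dims, sp, org, pos, amp, sigma)  # all nuclei
  for (i in seq_along(tissues)) {
    tis <- tissues[[i]]
    # shell around the ellipsoid surface, ~1 um thick
    geoMean <- prod(tis$semiaxes)^(1 / 3)
    distApprox <- (sqrt(qList[[i]]) - 1) * geoMean
    scene <- scene + 60 * exp(-distApprox^2 / (2 * 1.0^2))
  }
  scene <- scene + 15 * (qList[[1]] <= 1)  # faint interior absorption
  ctScene <- Volume(scene, spacing = sp, origin = org)

  ## ---- true transform and warp -----------------------------------------
  sRel <- spec@shrinkageScale
  R <- rotation3d(spec@rotationAxis, spec@rotationAngle)
  cFix <- extent / 2
  cCt <- cFix * sRel + spec@translation
  # A maps CT world -> fixed world with scale 1/sRel (> 1: specimen shrank)
  A <- similarityFromComponents(scale = 1 / sRel, rotation = R,
                                translation = cFix - (1 / sRel) *
                                  as.vector(R %*% cCt))
  warp <- NULL
  if (spec@warpAmplitude > 0 && spec@nWarpComponents > 0) {
    nodeSpacing <- max(extent) / 7
    nNodes <- ceiling(extent / nodeSpacing) + 1
    nodes <- lapply(1:3, function(a) nodeSpacing * (seq_len(nNodes[a]) - 1))
    vec <- array(0, c(nNodes, 3))
    for (mth in seq_len(spec@nWarpComponents)) {
      k <- sample(1:2, 3, replace = TRUE)
      # fundamental-dominated: amplitude falls off with frequency, which
      # keeps the warp smooth and invertible (|grad d| well below 1)
      ampPer <- spec@warpAmplitude / spec@nWarpComponents / max(k)
      phi <- stats::runif(3, 0, 2 * pi)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      s1 <- sin(2 * pi * k[1] * nodes[[1]] / extent[1] + phi[1])
      s2 <- sin(2 * pi * k[2] * nodes[[2]] / extent[2] + phi[2])
      s3 <- sin(2 * pi * k[3] * nodes[[3]] / extent[3] + phi[3])
      w3 <- outer(outer(s1, s2), s3)
      for (c in 1:3) vec[, , , c] <- vec[, , , c] + ampPer * u[c] * w3
    }
    warp <- displacementField(vec, nodeSpacing = nodeSpacing,
                              origin = c(0, 0, 0))
  }
  composite <- if (is.null(warp)) composeTransforms(A) else
    composeTransforms(warp, A)

  ## ---- render the CT volume on its own coarse grid ---------------------
  body <- tissues[[1L]]
  pad <- spec@warpAmplitude + 3
  cornersF <- as.matrix(expand.grid(
    body$center[1] + c(-1, 1) * (body$semiaxes[1] + pad),
    body$center[2] + c(-1, 1) * (body$semiaxes[2] + pad),
    body$center[3] + c(-1, 1) * (body$semiaxes[3] + pad)))
  cornersM <- invertPoints(composite, cornersF, tol = 1e-6, maxIter = 50L)
  ctSp <- spec@ctSpacing
  ctOrigin <- floor(apply(cornersM, 2, min) / ctSp) * ctSp - 2 * ctSp
  ctDims <- as.integer(ceiling((apply(cornersM, 2, max) - ctOrigin) /
                                 ctSp)) + 3L
  i1 <- seq_len(ctDims[1]) - 1L
  i2 <- seq_len(ctDims[2]) - 1L
  i3 <- seq_len(ctDims[3]) - 1L
  ctPts <- cbind(rep(i1, times = ctDims[2] * ctDims[3]),
                 rep(rep(i2, each = ctDims[1]), times = ctDims[3]),
                 rep(i3, each = ctDims[1] * ctDims[2]))
  ctPts <- sweep(ctPts * ctSp, 2, ctOrigin, "+")
  mapped <- applyToPoints(composite, ctPts)   # CT voxel -> fixed world
  idx <- mapped / sp                          # fixed grid is origin 0
  vals <- cpp_sample_volume(as.vector(scene), as.integer(dims), idx,
                            0L, FALSE, 0)
  if (spec@noiseSigmaCt > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, spec@noiseSigmaCt)
  }
  ct <- Volume(array(vals, ctDims), spacing = ctSp, origin = ctOrigin,
               dtypeTag = "float32")

  ## ---- landmarks --------------------------------------------------------
  centroids <- t(vapply(tissues, `[[`, numeric(3), "center"))
  nExtra <- max(0L, 8L - nrow(centroids))
  extra <- matrix(0, nExtra, 3)
  for (n in seq_len(nExtra)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    extra[n, ] <- body$center + 0.8 * body$semiaxes * u
  }
  lmFixed <- rbind(centroids, extra)
  lmMoving <- invertPoints(composite, lmFixed, tol = 1e-9, maxIter = 100L)
  lmNames <- c(vapply(tissues, `[[`, character(1), "name"),
               if (nExtra) paste0("interior", seq_len(nExtra)))
  landmarks <- landmarkSet(lmFixed, lmMoving, labels = lmNames)
  heldFixed <- matrix(0, 10, 3)
  for (n in 1:10) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    heldFixed[n, ] <- body$center + 0.8 * body$semiaxes * u
  }
  heldMoving <- invertPoints(composite, heldFixed, tol = 1e-9,
                             maxIter = 100L)
  heldout <- landmarkSet(heldFixed, heldMoving)

  nuclei <- data.frame(pos1 = pos[, 1], pos2 = pos[, 2], pos3 = pos[, 3],
                       tissue = nucLabel)
  for (m in seq_along(spec@markerMaps)) {
    nuclei[[spec@markerMaps[[m]]$name]] <- exprMat[, m]
  }

  list(spim = spim, ct = ct, labels = labels,
       truth = list(transform = A, warp = warp, composite = composite,
                    landmarks = landmarks, heldout = heldout,
                    nuclei = nuclei, ctScene = ctScene,
                    shrinkagePercent = (1 - sRel) * 100))
}
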