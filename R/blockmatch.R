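#' Construct block-matching parameters
#'
#' @param blockSize voxels per block side.
#' @param blockStride stride between blocks, voxels.
#' @param searchRadius exhaustive integer-displacement search radius,
#'   voxels.
#' @param iterations block-match/fit rounds per pyramid level. The
#'   default of 20 is the iteration count this registration stage is run
#'   with in practice.
#' @param varianceFloor minimum fixed-block intensity variance for a
#'   block to take part in matching; \code{NA} (default) uses the 10th
#'   percentile of all block variances, so background blocks in sparse
#'   fluorescence data cannot dominate with spurious matches.
#' @param trimFraction fraction of worst correspondences discarded by the
#'   robust similarity fit.
#' @param pyramidLevels coarse-to-fine levels; level \code{l} bins the
#'   volumes by \code{2^(l-1)}.
#' @return a [BlockMatchParams-class].
#' @export
blockMatchParams <- function(blockSize = 8L, blockStride = 8L,
                             searchRadius = 4L, iterations = 20L,
                             varianceFloor = NA_real_,
                             trimFraction = 0.25, pyramidLevels = 3L) {
  new("BlockMatchParams", blockSize = as.integer(blockSize),
      blockStride = as.integer(blockStride),
      searchRadius = as.integer(searchRadius),
      iterations = as.integer(iterations),
      varianceFloor = as.double(varianceFloor),
      trimFraction = as.double(trimFraction),
      pyramidLevels = as.integer(pyramidLevels))
}

setMethod("show", "BlockMatchParams", function(object) {
  cat(sprintf(paste0("BlockMatchParams: block %d, stride %d, radius %d, ",
                     "%d iterations, trim %.2f, %d pyramid level(s)\n"),
              object@blockSize, object@blockStride, object@searchRadius,
              object@iterations, object@trimFraction, object@pyramidLevels))
})

.resolveVarianceFloor <- function(fixed, p) {
  vars <- cpp_block_variances(as.vector(fixed@data),
                              as.integer(dim(fixed@data)),
                              p@blockSize, p@blockStride)
  if (length(vars) == 0L) {
    stop("volume smaller than one block; reduce blockSize")
  }
  if (is.na(p@varianceFloor)) {
    # keep the top quartile of block variances: in sparse fluorescence
    # data most blocks are background, and background matches are noise
    stats::quantile(vars, 0.75, names = FALSE)
  } else {
    p@varianceFloor
  }
}

#' Block-matching correspondence search
#'
#' For each eligible block of the fixed volume (intensity variance at or
#' above the floor), exhaustively searches integer displacements within
#' the search radius in the moving volume, scoring each by normalized
#' cross-correlation (NCC). NCC is used because the two modalities share
#' structure but not intensity scale: it is invariant to affine intensity
#' maps. The argmax displacement is returned per block; ties are broken
#' by smallest displacement norm, then lexicographic order. Moving
#' windows with no variance have undefined NCC and score -2.
#'
#' Sub-voxel accuracy comes from the pyramid and from least-squares
#' averaging over many blocks, not from per-block interpolation: the
#' per-block search is integer-displacement only.
#'
#' @param fixed,moving [Volume-class]s on the same grid (the moving
#'   volume already resampled by the current transform estimate).
#' @param params a [BlockMatchParams-class].
#' @return a data frame (one row per eligible block) with block centres
#'   in fixed-space um (\code{c1..c3}), matched displacements in um
#'   (\code{d1..d3}) and NCC scores.
#' @export
matchBlocks <- function(fixed, moving, params = blockMatchParams()) {
  stopifnot(is(fixed, "Volume"), is(moving, "Volume"))
  if (!identical(dim(fixed@data), dim(moving@data)) ||
      abs(fixed@spacing - moving@spacing) > 1e-9) {
    stop("fixed and moving must share grid shape and spacing")
  }
  floorv <- .resolveVarianceFloor(fixed, params)
  m <- cpp_match_blocks(as.vector(fixed@data), as.vector(moving@data),
                        as.integer(dim(fixed@data)), params@blockSize,
                        params@blockStride, params@searchRadius, floorv)
  if (nrow(m) == 0L) {
    stop("no textured blocks; lower variance_floor")
  }
  sp <- fixed@spacing
  centerIdx <- m[, 1:3, drop = FALSE] + (params@blockSize - 1) / 2
  centers <- sweep(centerIdx * sp, 2, fixed@origin, "+")
  data.frame(c1 = centers[, 1], c2 = centers[, 2], c3 = centers[, 3],
             d1 = m[, 4] * sp, d2 = m[, 5] * sp, d3 = m[, 6] * sp,
             score = m[, 7])
}

#' Robust similarity fit to a correspondence field
#'
#' Iterated trimmed least squares: fits a similarity transform to the
#' pairs (centre -> centre + displacement), recomputes residuals over
#' all pairs, keeps the \code{1 - trimFraction} fraction with smallest
#' residuals, and refits until the inlier set stabilises (at most 10
#' rounds). With \code{trimFraction = 0} on an outlier-free exact field
#' this reproduces the closed-form landmark fit exactly.
#'
#' @param correspondences data frame from [matchBlocks()].
#' @param trimFraction fraction of worst correspondences dropped.
#' @return list with \code{transform} (a [SimilarityTransform-class]
#'   mapping centre to centre + displacement), \code{rmsResidual} (um,
#'   over inliers), \code{inliers} (logical vector) and \code{rounds}.
#' @export
robustFit <- function(correspondences, trimFraction = 0.25) {
  cc <- as.matrix(correspondences[, c("c1", "c2", "c3")])
  dd <- as.matrix(correspondences[, c("d1", "d2", "d3")])
  n <- nrow(cc)
  m <- ceiling((1 - trimFraction) * n)
  if (m < 5L) stop("fewer than 5 correspondences survive trimming")
  X <- cc
  Y <- cc + dd
  inl <- seq_len(n)
  fit <- NULL
  rounds <- 0L
  for (r in seq_len(10L)) {
    rounds <- r
    fit <- estimateSimilarity(landmarkSet(Y[inl, , drop = FALSE],
                                          X[inl, , drop = FALSE]))
    res <- sqrt(rowSums((.applySimilarity(fit$transform, X) - Y)^2))
    newInl <- order(res)[seq_len(m)]
    if (setequal(newInl, inl)) break
    inl <- newInl
  }
  if (length(inl) < 5L) stop("fewer than 5 correspondences survive trimming")
  inliers <- rep(FALSE, n)
  inliers[inl] <- TRUE
  res <- sqrt(rowSums((.applySimilarity(fit$transform, X) - Y)^2))
  list(transform = fit$transform,
       rmsResidual = sqrt(mean(res[inl]^2)),
       inliers = inliers, rounds = rounds)
}

#' Coarse-to-fine block-matching similarity registration
#'
#' Refines an initial similarity (typically the landmark fit) by
#' repeated block matching over a multiresolution pyramid. At each level
#' (binned by 2 per level, coarse to fine) the loop is: resample the
#' moving volume with the current transform onto the level grid; match
#' blocks; robustly fit a similarity to the correspondence field;
#' compose the correction with the current transform. The loop stops
#' early when the mean correspondence displacement falls below 0.1
#' voxel, and aborts with a diagnostic log if the mean displacement
#' grows three iterations in a row (a gross mis-initialisation should
#' fail loudly, not return a silently wrong answer). The whole procedure
#' is deterministic given its inputs.
#'
#' @param fixed fixed [Volume-class] (light-sheet side).
#' @param moving moving [Volume-class] (tomography side), any grid.
#' @param init initial [SimilarityTransform-class] mapping moving to
#'   fixed world coordinates.
#' @param params a [BlockMatchParams-class].
#' @return list with \code{transform} (final
#'   [SimilarityTransform-class]), \code{residuals} (per-level list of
#'   per-iteration mean correspondence displacements, in level voxels),
#'   \code{converged} (logical) and \code{levels} (binning factors used).
#' @export
registerSimilarity <- function(fixed, moving,
                               init = similarityTransform(),
                               params = blockMatchParams()) {
  stopifnot(is(fixed, "Volume"), is(moving, "Volume"))
  current <- init
  residLog <- list()
  levelsUsed <- integer()
  converged <- FALSE
  for (lev in seq(params@pyramidLevels, 1L)) {
    factor <- 2L^(lev - 1L)
    d <- dim(fixed@data) %/% factor
    if (any(d < params@blockSize)) next  # level smaller than one block
    fixedL <- if (factor > 1L) binVolume(fixed, factor) else fixed
    # a level is usable only if enough textured blocks survive the floor
    # and the trimming to constrain a similarity fit
    vars <- cpp_block_variances(as.vector(fixedL@data),
                                as.integer(dim(fixedL@data)),
                                params@blockSize, params@blockStride)
    floorL <- if (is.na(params@varianceFloor)) {
      stats::quantile(vars, 0.75, names = FALSE)
    } else params@varianceFloor
    nElig <- sum(vars >= floorL & vars > 1e-12)
    if (ceiling((1 - params@trimFraction) * nElig) < 5L) next
    levelsUsed <- c(levelsUsed, factor)
    lres <- numeric()
    grow <- 0L
    prev <- Inf
    for (it in seq_len(params@iterations)) {
      movL <- resampleVolume(moving, current, fixedL, "linear")
      corr <- matchBlocks(fixedL, movL, params)
      if (stats::median(corr$score) <= 0) {
        residLog[[length(residLog) + 1L]] <- lres
        stop(errorCondition(
          paste0("registration diverged: no cross-modal agreement at ",
                 "level ", factor, " (median NCC <= 0); the initial ",
                 "transform probably does not overlap the volumes"),
          residuals = residLog, class = "voxalignDivergence"))
      }
      meanDispVox <- mean(sqrt(corr$d1^2 + corr$d2^2 + corr$d3^2)) /
        fixedL@spacing
      lres <- c(lres, meanDispVox)
      if (meanDispVox > prev * 1.05) grow <- grow + 1L else grow <- 0L
      if (grow >= 3L) {
        residLog[[length(residLog) + 1L]] <- lres
        cond <- errorCondition(
          paste0("registration diverged: mean correspondence displacement ",
                 "grew 3 iterations in a row at level ", factor),
          residuals = residLog, class = "voxalignDivergence")
        stop(cond)
      }
      prev <- meanDispVox
      if (meanDispVox < 0.1) { converged <- TRUE; break }
      if (it >= 6L && min(lres[(it - 4L):it]) > min(lres[1:(it - 5L)])) {
        # plateau: no improvement over 5 iterations; the matches are at
        # their quantization floor
        converged <- TRUE
        break
      }
      corrFit <- robustFit(corr, params@trimFraction)
      # stop when the fitted correction barely moves the level domain:
      # the integer matches are frozen at their quantization floor and
      # further iterations cannot improve the estimate
      cornerIdx <- as.matrix(expand.grid(c(0, dim(fixedL@data)[1] - 1),
                                         c(0, dim(fixedL@data)[2] - 1),
                                         c(0, dim(fixedL@data)[3] - 1)))
      corners <- sweep(cornerIdx * fixedL@spacing, 2, fixedL@origin, "+")
      motion <- max(sqrt(rowSums(
        (.applySimilarity(corrFit$transform, corners) - corners)^2)))
      if (motion < 0.05 * fixedL@spacing) {
        converged <- TRUE
        break
      }
      # S maps centre -> centre + displacement in fixed space, so the
      # updated moving->fixed map is S^{-1} composed after the current
      current <- similarityTransform(
        invertSimilarity(corrFit$transform)@matrix %*% current@matrix)
    }
    residLog[[length(residLog) + 1L]] <- lres
  }
  if (length(levelsUsed) == 0L) {
    stop("volume too small for the requested block size at every level")
  }
  list(transform = current, residuals = residLog, converged = converged,
       levels = levelsUsed)
}

## separable Gaussian smoothing of a lattice of vectors with per-node
## weights (eligible = 1, missing = 0): smoothing and hole-filling in one
## normalized convolution
.smoothLattice <- function(vec, w, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  d <- dim(vec)[1:3]
  convAxis <- function(a, axis) {
    n <- d[axis]
    out <- array(0, dim(a))
    for (o in seq(-r, r)) {
      srcIdx <- seq_len(n) + o
      ok <- srcIdx >= 1L & srcIdx <= n
      if (!any(ok)) next
      srcIdx[!ok] <- 1L            # placeholder, zeroed via mask
      mask <- as.numeric(ok)
      shifted <- switch(axis,
                        a[srcIdx, , , drop = FALSE] *
                          mask[slice.index(a, 1L)],
                        a[, srcIdx, , drop = FALSE] *
                          mask[slice.index(a, 2L)],
                        a[, , srcIdx, drop = FALSE] *
                          mask[slice.index(a, 3L)])
      out <- out + g[o + r + 1L] * shifted
    }
    out
  }
  conv3 <- function(a) convAxis(convAxis(convAxis(a, 1L), 2L), 3L)
  wS <- conv3(w)
  out <- array(0, dim(vec))
  for (c in 1:3) {
    comp <- vec[, , , c]
    dim(comp) <- d
    num <- conv3(comp * w)
    sm <- num / wS
    sm[wS <= 0] <- 0
    out[, , , c] <- sm
  }
  out
}

#' Dense displacement-field refinement
#'
#' One block-matching pass on a node lattice after the similarity stage
#' has converged (the two stages are not interleaved: the global fit
#' first, then the residual field). Raw node vectors are regularised by
#' a Gaussian (sigma = 1 node) normalized convolution, which also fills
#' ineligible (textureless) nodes from their neighbours; a perfectly
#' aligned pair yields a (near) zero field. The node vectors stored in
#' the returned field are oriented so that resampling the moving volume
#' through \code{composeTransforms(field, similarity)} reads each fixed
#' voxel at its matched moving location.
#'
#' @param fixed fixed [Volume-class].
#' @param movingResampled moving volume already resampled onto the fixed
#'   grid by the similarity stage.
#' @param params a [BlockMatchParams-class]; the node spacing is
#'   \code{blockStride * spacing(fixed)}.
#' @return a [DisplacementField-class] in fixed space.
#' @export
refineDense <- function(fixed, movingResampled,
                        params = blockMatchParams()) {
  stopifnot(is(fixed, "Volume"), is(movingResampled, "Volume"))
  if (!identical(dim(fixed@data), dim(movingResampled@data))) {
    stop("fixed and movingResampled must share a grid")
  }
  d <- dim(fixed@data)
  b <- params@blockSize
  st <- params@blockStride
  starts <- lapply(d, function(n) seq(0L, n - b, by = st))
  nl <- vapply(starts, length, integer(1))
  if (any(nl < 1L)) stop("volume smaller than one block; reduce blockSize")
  floorv <- .resolveVarianceFloor(fixed, params)
  m <- cpp_match_blocks(as.vector(fixed@data),
                        as.vector(movingResampled@data),
                        as.integer(d), b, st, params@searchRadius, floorv)
  if (nrow(m) == 0L) stop("no textured blocks; lower variance_floor")
  vec <- array(0, c(nl, 3))
  w <- array(0, nl)
  sp <- fixed@spacing
  for (r in seq_len(nrow(m))) {
    i <- match(m[r, 1], starts[[1]])
    j <- match(m[r, 2], starts[[2]])
    k <- match(m[r, 3], starts[[3]])
    # store the negated match vector: the field warp W must satisfy
    # W^{-1}(c) = c + delta(c), i.e. d(W^{-1}(c)) = -delta, approximated
    # at the node itself (first order in the smooth residual)
    vec[i, j, k, ] <- -m[r, 4:6] * sp
    w[i, j, k] <- 1
  }
  sm <- .smoothLattice(vec, w, sigma = 1)
  centerOff <- (b - 1) / 2
  originField <- fixed@origin + sp * centerOff
  displacementField(sm, nodeSpacing = st * sp, origin = originField)
}
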