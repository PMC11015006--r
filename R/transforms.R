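#' Construct a SimilarityTransform
#'
#' @param matrix 4x4 homogeneous matrix (world um); linear part must be
#'   isotropic scale times a proper rotation.
#' @return a [SimilarityTransform-class].
#' @export
similarityTransform <- function(matrix = diag(4)) {
  new("SimilarityTransform", matrix = matrix * 1.0)
}

#' Build a similarity transform from components
#'
#' @param scale isotropic scale factor (> 0).
#' @param rotation 3x3 proper rotation matrix (see [rotation3d()]).
#' @param translation translation 3-vector, um.
#' @param center optional centre of rotation/scaling, um; the transform
#'   is then \code{x -> s R (x - center) + center + translation}.
#' @return a [SimilarityTransform-class].
#' @export
similarityFromComponents <- function(scale = 1, rotation = diag(3),
                                     translation = c(0, 0, 0),
                                     center = c(0, 0, 0)) {
  A <- scale * rotation
  t <- center + translation - A %*% center
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- t
  similarityTransform(m)
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation about a (not necessarily unit) axis.
#'
#' @param axis 3-vector rotation axis.
#' @param angleDeg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation3d <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Transform matrix accessor
#' @param t a [SimilarityTransform-class].
#' @return the 4x4 homogeneous matrix.
#' @export
transformMatrix <- function(t) t@matrix

#' Isotropic scale factor of a similarity transform
#' @param t a [SimilarityTransform-class].
#' @return the scalar \code{s} with linear part \code{s * R}.
#' @export
scaleFactor <- function(t) det(t@matrix[1:3, 1:3])^(1 / 3)

#' Exact inverse of a similarity transform
#' @param t a [SimilarityTransform-class].
#' @return its inverse [SimilarityTransform-class].
#' @export
invertSimilarity <- function(t) {
  A <- t@matrix[1:3, 1:3]
  b <- t@matrix[1:3, 4]
  Ai <- solve(A)
  m <- diag(4)
  m[1:3, 1:3] <- Ai
  m[1:3, 4] <- -Ai %*% b
  similarityTransform(m)
}

setMethod("show", "SimilarityTransform", function(object) {
  s <- scaleFactor(object)
  cat(sprintf("SimilarityTransform: scale %.6f, translation (%.3f, %.3f, %.3f) um\n",
              s, object@matrix[1, 4], object@matrix[2, 4],
              object@matrix[3, 4]))
})

#' Construct a DisplacementField
#'
#' @param vectors 4D array (n1, n2, n3, 3) of node vectors, um.
#' @param nodeSpacing lattice spacing, um.
#' @param origin world position (um) of node (0, 0, 0).
#' @return a [DisplacementField-class].
#' @export
displacementField <- function(vectors, nodeSpacing, origin = c(0, 0, 0)) {
  new("DisplacementField", vectors = vectors * 1.0,
      nodeSpacing = as.double(nodeSpacing), origin = as.double(origin))
}

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  nrm <- sqrt(apply(object@vectors^2, 1:3, sum))
  cat(sprintf("DisplacementField: %d x %d x %d nodes, spacing %.3f um, max |d| %.3f um\n",
              d[1], d[2], d[3], object@nodeSpacing, max(nrm)))
})

#' Construct a CompositeTransform
#'
#' @param stages list of [SimilarityTransform-class] /
#'   [DisplacementField-class] stages, applied right-to-left.
#' @return a [CompositeTransform-class].
#' @export
compositeTransform <- function(stages = list()) {
  new("CompositeTransform", stages = stages)
}

setMethod("show", "CompositeTransform", function(object) {
  cat(sprintf("CompositeTransform: %d stage(s)\n", length(object@stages)))
  for (s in object@stages) show(s)
})

setAs("SimilarityTransform", "CompositeTransform",
      function(from) compositeTransform(list(from)))
setAs("DisplacementField", "CompositeTransform",
      function(from) compositeTransform(list(from)))

#' Merge transforms into one composite
#'
#' Accepts any mix of similarity transforms, displacement fields and
#' composites, in application order right-to-left (like a matrix
#' product: the last argument is applied first). Adjacent similarity
#' stages are pre-multiplied into a single matrix; field stages are kept
#' as separate stages. The merged mapping equals sequential application.
#'
#' @param ... transforms, or a single list of transforms.
#' @return a [CompositeTransform-class].
#' @examples
#' t1 <- similarityFromComponents(scale = 2)
#' t2 <- similarityFromComponents(translation = c(1, 0, 0))
#' # right-to-left: translate first, then scale => origin maps to (2,0,0)
#' applyToPoints(composeTransforms(t1, t2), matrix(0, 1, 3))
#' @export
composeTransforms <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !is(args[[1L]], "SimilarityTransform") &&
      !is(args[[1L]], "DisplacementField")) {
    args <- args[[1L]]
  }
  flat <- list()
  for (a in args) {
    if (is(a, "CompositeTransform")) {
      flat <- c(flat, a@stages)
    } else if (is(a, "SimilarityTransform") || is(a, "DisplacementField")) {
      flat <- c(flat, list(a))
    } else {
      stop("cannot compose object of class ", class(a))
    }
  }
  merged <- list()
  for (st in flat) {
    n <- length(merged)
    if (n > 0L && is(st, "SimilarityTransform") &&
        is(merged[[n]], "SimilarityTransform")) {
      # merged[[n]] is applied after st? No: stages are listed
      # left-to-right but applied right-to-left, so st (appended later)
      # is applied before merged[[n]]: product merged[[n]] %*% st.
      merged[[n]] <- similarityTransform(merged[[n]]@matrix %*% st@matrix)
    } else {
      merged[[n + 1L]] <- st
    }
  }
  compositeTransform(merged)
}

## interpolate field vectors at world points (clamped edge extension)
.fieldAt <- function(field, pts) {
  idx <- sweep(pts, 2, field@origin, "-") / field@nodeSpacing
  d <- dim(field@vectors)[1:3]
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    comp <- field@vectors[, , , c, drop = TRUE]
    dim(comp) <- d
    out[, c] <- cpp_sample_volume(as.vector(comp), as.integer(d), idx,
                                  0L, TRUE, 0)
  }
  out
}

.applySimilarity <- function(t, pts) {
  A <- t@matrix[1:3, 1:3]
  b <- t@matrix[1:3, 4]
  sweep(pts %*% t(A), 2, b, "+")
}

#' @rdname applyToPoints
#' @export
setMethod("applyToPoints", "SimilarityTransform", function(transform, points) {
  .applySimilarity(transform, rbind(points) * 1.0)
})

#' @rdname applyToPoints
#' @export
setMethod("applyToPoints", "DisplacementField", function(transform, points) {
  points <- rbind(points) * 1.0
  points + .fieldAt(transform, points)
})

#' @rdname applyToPoints
#' @export
setMethod("applyToPoints", "CompositeTransform", function(transform, points) {
  points <- rbind(points) * 1.0
  for (st in rev(transform@stages)) {
    points <- applyToPoints(st, points)
  }
  points
})

.invertFieldPoints <- function(field, pts, tol, maxIter) {
  y <- pts
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ynew <- pts - .fieldAt(field, y)
    delta <- max(abs(ynew - y))
    y <- ynew
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(y, "converged") <- converged
  y
}

#' @rdname invertPoints
#' @export
setMethod("invertPoints", "SimilarityTransform",
          function(transform, points, tol = 1e-6, maxIter = 20L) {
  out <- .applySimilarity(invertSimilarity(transform), rbind(points) * 1.0)
  attr(out, "converged") <- TRUE
  out
})

#' @rdname invertPoints
#' @export
setMethod("invertPoints", "DisplacementField",
          function(transform, points, tol = 1e-6, maxIter = 20L) {
  .invertFieldPoints(transform, rbind(points) * 1.0, tol, maxIter)
})

#' @rdname invertPoints
#' @export
setMethod("invertPoints", "CompositeTransform",
          function(transform, points, tol = 1e-6, maxIter = 20L) {
  pts <- rbind(points) * 1.0
  conv <- TRUE
  for (st in transform@stages) {  # forward order = reversed inverse
    pts <- invertPoints(st, pts, tol = tol, maxIter = maxIter)
    conv <- conv && isTRUE(attr(pts, "converged"))
  }
  attr(pts, "converged") <- conv
  pts
})

#' Estimate a similarity transform from paired landmarks
#'
#' Closed-form least-squares absolute orientation (SVD of the paired
#' cross-covariance, with isotropic scale): finds the rotation, scale
#' and translation minimising \eqn{\sum_i \| T(m_i) - f_i \|^2} over
#' the landmark pairs. Chosen for determinism -- no iterative solver.
#' If the SVD yields a reflection (det < 0) the smallest singular axis
#' is flipped, the standard correction: landmark click errors must not
#' produce mirror registrations. At least 5 non-degenerate pairs are
#' required.
#'
#' @param lm a [LandmarkSet-class] with at least 5 pairs.
#' @param minPairs minimum number of pairs (default 5).
#' @return list with elements \code{transform} (a
#'   [SimilarityTransform-class] mapping moving to fixed) and
#'   \code{rmsResidual} (um).
#' @examples
#' set.seed(1)
#' f <- matrix(runif(15, 0, 50), 5, 3)
#' lm <- landmarkSet(f, f)
#' estimateSimilarity(lm)$rmsResidual  # 0: identical point sets
#' @export
estimateSimilarity <- function(lm, minPairs = 5L) {
  stopifnot(is(lm, "LandmarkSet"))
  X <- lm@movingPoints
  Y <- lm@fixedPoints
  n <- nrow(X)
  if (n < minPairs) {
    stop("minimum of ", minPairs, " landmark pairs required, got ", n)
  }
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sigx2 <- mean(rowSums(Xc^2))
  if (sigx2 < 1e-12) stop("degenerate landmark configuration (coincident points)")
  Sxy <- crossprod(Yc, Xc) / n   # sum (y - my)(x - mx)^T / n
  sv <- svd(Sxy)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)) {
    stop("degenerate landmark configuration (rank-deficient: points collinear)")
  }
  dsign <- sign(det(sv$u %*% t(sv$v)))
  if (dsign == 0) dsign <- 1
  S <- c(1, 1, dsign)
  R <- sv$u %*% diag(S) %*% t(sv$v)
  s <- sum(sv$d * S) / sigx2
  t <- my - s * as.vector(R %*% mx)
  tr <- similarityFromComponents(scale = s, rotation = R, translation = t)
  res <- .applySimilarity(tr, X) - Y
  list(transform = tr, rmsResidual = sqrt(mean(rowSums(res^2))))
}

#' Resample a volume through a transform onto a reference grid
#'
#' Pull-back convention: \code{output(x) = moving(T^{-1}(x))} for every
#' voxel centre x of the reference grid. Affine stages are inverted
#' exactly; displacement-field stages by fixed-point iteration (at most
#' 20 iterations, tolerance 0.01 reference voxel); non-convergence
#' raises a warning and falls back to the last iterate, flagged in the
#' \code{"fieldInversionConverged"} attribute. Out-of-domain voxels are
#' set to 0. Use linear interpolation for intensities and nearest for
#' label volumes.
#'
#' @param moving a [Volume-class] (the volume being mapped).
#' @param transform transform mapping moving world to fixed world.
#' @param reference a [Volume-class] or [LabelVolume-class] defining the
#'   output grid.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return a [Volume-class] on the reference grid.
#' @export
resampleVolume <- function(moving, transform,
                           reference, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(moving, "Volume"))
  transform <- if (is(transform, "CompositeTransform")) transform else
    as(transform, "CompositeTransform")
  rd <- gridDims(reference)
  # zero-based index grid of the reference, expanded in array order
  i1 <- seq_len(rd[1]) - 1L
  i2 <- seq_len(rd[2]) - 1L
  i3 <- seq_len(rd[3]) - 1L
  pts <- cbind(rep(i1, times = rd[2] * rd[3]),
               rep(rep(i2, each = rd[1]), times = rd[3]),
               rep(i3, each = rd[1] * rd[2]))
  pts <- sweep(pts * spacing(reference), 2, origin(reference), "+")
  tol <- 0.01 * spacing(reference)
  pre <- invertPoints(transform, pts, tol = tol, maxIter = 20L)
  conv <- isTRUE(attr(pre, "converged"))
  if (!conv) {
    warning("displacement-field inversion did not converge everywhere; ",
            "using last iterate")
  }
  idx <- sweep(pre, 2, moving@origin, "-") / moving@spacing
  mode <- if (interpolation == "linear") 0L else 1L
  vals <- cpp_sample_volume(as.vector(moving@data),
                            as.integer(dim(moving@data)), idx, mode,
                            FALSE, 0)
  out <- Volume(array(vals, rd), spacing = spacing(reference),
                origin = origin(reference),
                dtypeTag = if (interpolation == "nearest") moving@dtypeTag
                           else "float32")
  attr(out, "fieldInversionConverged") <- conv
  out
}
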