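#' Checkerboard composite of two registered volumes
#'
#' Extracts the same 2D section from both volumes and assembles a
#' checkerboard: tile (i, j) shows the fixed volume when i + j is even
#' and the registered moving volume when odd, each source independently
#' rescaled to 8-bit for display. Continuous structures across tile
#' borders indicate good alignment. Every pixel comes from exactly one
#' source.
#'
#' @param fixed,registeredMoving [Volume-class]s on identical grids.
#' @param tile tile edge length in voxels (>= 1).
#' @param sliceAxis axis (1 = depth, 2 = row, 3 = column) normal to the
#'   section.
#' @param sliceIndex 1-based slice index along \code{sliceAxis}; default
#'   the mid-plane.
#' @return integer matrix of 8-bit display values, with attribute
#'   \code{"source"} (0 = fixed, 1 = moving per pixel).
#' @export
checkerboard <- function(fixed, registeredMoving, tile = 32L,
                         sliceAxis = 1L, sliceIndex = NULL) {
  stopifnot(is(fixed, "Volume"), is(registeredMoving, "Volume"))
  if (!identical(dim(fixed@data), dim(registeredMoving@data))) {
    stop("fixed and registeredMoving must share a grid")
  }
  tile <- as.integer(tile)
  if (tile < 1L) stop("tile must be >= 1")
  d <- dim(fixed@data)
  if (is.null(sliceIndex)) sliceIndex <- (d[sliceAxis] + 1L) %/% 2L
  slice2d <- function(v) {
    switch(sliceAxis,
           matrix(v@data[sliceIndex, , ], d[2], d[3]),
           matrix(v@data[, sliceIndex, ], d[1], d[3]),
           matrix(v@data[, , sliceIndex], d[1], d[2]))
  }
  rescale8 <- function(m) {
    rng <- range(m)
    if (rng[2] <= rng[1]) return(matrix(0L, nrow(m), ncol(m)))
    matrix(as.integer(floor((m - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)),
           nrow(m), ncol(m))
  }
  f8 <- rescale8(slice2d(fixed))
  m8 <- rescale8(slice2d(registeredMoving))
  ti <- (row(f8) - 1L) %/% tile
  tj <- (col(f8) - 1L) %/% tile
  fromMoving <- (ti + tj) %% 2L == 1L
  out <- f8
  out[fromMoving] <- m8[fromMoving]
  attr(out, "source") <- fromMoving * 1L
  out
}

#' Target registration error over held-out landmarks
#'
#' The quantitative twin of the checkerboard check: the distance between
#' each held-out fixed landmark and the image of its moving partner
#' under the estimated transform.
#'
#' @param transform estimated moving-to-fixed transform.
#' @param heldout a [LandmarkSet-class] of pairs not used in fitting
#'   (at least one pair).
#' @return list with \code{mean}, \code{max} (um) and
#'   \code{perLandmark} distances.
#' @export
targetRegistrationError <- function(transform, heldout) {
  stopifnot(is(heldout, "LandmarkSet"))
  if (nrow(heldout@fixedPoints) < 1L) {
    stop("at least one held-out landmark pair is required")
  }
  mapped <- applyToPoints(transform, heldout@movingPoints)
  d <- sqrt(rowSums((mapped - heldout@fixedPoints)^2))
  list(mean = mean(d), max = max(d), perLandmark = d)
}

#' Construct a RegistrationReport
#'
#' @param rmsLandmarkResidual RMS landmark-fit residual, um.
#' @param treHeldout mean held-out TRE, um (NA if none).
#' @param perIterationResiduals per-level list of per-iteration mean
#'   correspondence displacements (level voxels).
#' @param shrinkage linear shrinkage percent of the fitted similarity.
#' @param warnings character vector of diagnostics.
#' @return a [RegistrationReport-class].
#' @export
registrationReport <- function(rmsLandmarkResidual = NA_real_,
                               treHeldout = NA_real_,
                               perIterationResiduals = list(),
                               shrinkage = NA_real_,
                               warnings = character()) {
  new("RegistrationReport",
      rmsLandmarkResidual = as.double(rmsLandmarkResidual),
      treHeldout = as.double(treHeldout),
      perIterationResiduals = perIterationResiduals,
      shrinkage = as.double(shrinkage), warnings = warnings)
}

setMethod("show", "RegistrationReport", function(object) {
  cat("RegistrationReport\n")
  cat(sprintf("  landmark fit RMS: %.3f um\n", object@rmsLandmarkResidual))
  cat(sprintf("  held-out TRE:     %.3f um\n", object@treHeldout))
  cat(sprintf("  shrinkage:        %.2f %%\n", object@shrinkage))
  nIt <- sum(lengths(object@perIterationResiduals))
  cat(sprintf("  refinement iterations: %d\n", nIt))
  if (length(object@warnings)) {
    cat("  warnings:\n")
    for (w in object@warnings) cat("   -", w, "\n")
  }
})
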