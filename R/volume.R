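#' Construct a Volume
#'
#' @param data numeric 3D array in depth--row--column order.
#' @param spacing isotropic voxel edge length, um.
#' @param origin world position (um) of the centre of voxel (0, 0, 0).
#' @param dtypeTag sample format tag: \code{"uint8"}, \code{"uint16"} or
#'   \code{"float32"}.
#' @return a [Volume-class] object.
#' @examples
#' v <- Volume(array(0:7, c(2, 2, 2)), spacing = 1.22)
#' spacing(v)
#' @export
Volume <- function(data, spacing, origin = c(0, 0, 0),
                   dtypeTag = "float32") {
  if (is.null(dim(data))) stop("data must be a 3D array")
  new("Volume", data = array(as.double(data), dim(data)),
      spacing = as.double(spacing), origin = as.double(origin),
      dtypeTag = dtypeTag)
}

#' Construct a MultiChannelVolume
#'
#' @param channels list of [Volume-class] objects on identical grids.
#' @param names channel labels; defaults to \code{chan1, chan2, ...}.
#' @return a [MultiChannelVolume-class] object.
#' @export
MultiChannelVolume <- function(channels, names = NULL) {
  if (is(channels, "Volume")) channels <- list(channels)
  if (is.null(names)) names <- paste0("chan", seq_along(channels))
  new("MultiChannelVolume", channels = channels, names = as.character(names))
}

#' @rdname spacing
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "MultiChannelVolume",
          function(x) x@channels[[1L]]@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "DisplacementField", function(x) x@nodeSpacing)

#' @rdname origin
#' @export
setMethod("origin", "Volume", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "MultiChannelVolume", function(x) x@channels[[1L]]@origin)
#' @rdname origin
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' @rdname voxelData
#' @export
setMethod("voxelData", "Volume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)

#' @rdname gridDims
#' @export
setMethod("gridDims", "Volume", function(x) dim(x@data))
#' @rdname gridDims
#' @export
setMethod("gridDims", "LabelVolume", function(x) dim(x@data))
#' @rdname gridDims
#' @export
setMethod("gridDims", "MultiChannelVolume",
          function(x) dim(x@channels[[1L]]@data))

#' Sample-format tag of a volume
#' @param x a [Volume-class].
#' @return one of \code{"uint8"}, \code{"uint16"}, \code{"float32"}.
#' @export
dtypeTag <- function(x) x@dtypeTag

#' Channels of a MultiChannelVolume
#' @param x a [MultiChannelVolume-class].
#' @return list of [Volume-class] objects.
#' @export
channels <- function(x) {
  stats::setNames(x@channels, x@names)
}

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d (depth x row x col), %s\n",
              d[1], d[2], d[3], object@dtypeTag))
  cat(sprintf("  spacing %.6f um, origin (%.6f, %.6f, %.6f) um\n",
              object@spacing, object@origin[1], object@origin[2],
              object@origin[3]))
  rng <- range(object@data)
  cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "MultiChannelVolume", function(object) {
  d <- dim(object@channels[[1L]]@data)
  cat(sprintf("MultiChannelVolume: %d channel(s) [%s], %d x %d x %d, %.6f um\n",
              length(object@channels), paste(object@names, collapse = ", "),
              d[1], d[2], d[3], object@channels[[1L]]@spacing))
})

#' World coordinates of voxel indices
#'
#' @param v a [Volume-class] or [LabelVolume-class].
#' @param idx n x 3 matrix of zero-based voxel indices (depth, row, col).
#' @return n x 3 matrix of world coordinates (um):
#'   \code{origin + spacing * idx}.
#' @export
voxelToWorld <- function(v, idx) {
  idx <- rbind(idx)
  sweep(idx * spacing(v), 2, origin(v), "+")
}

#' Voxel indices (continuous, zero-based) of world coordinates
#'
#' @param v a [Volume-class] or [LabelVolume-class].
#' @param pts n x 3 matrix of world coordinates (um).
#' @return n x 3 matrix of continuous zero-based voxel indices.
#' @export
worldToVoxel <- function(v, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, origin(v), "-") / spacing(v)
}

#' Crop a volume to an index box
#'
#' Copies the voxels with zero-based indices in \code{[lo, hi)} per axis
#' and shifts the origin by \code{spacing * lo}, so world coordinates of
#' the retained voxels are unchanged.
#'
#' @param v a [Volume-class].
#' @param lo integer 3-vector, zero-based inclusive lower corner.
#' @param hi integer 3-vector, zero-based exclusive upper corner.
#' @return the cropped [Volume-class].
#' @export
cropVolume <- function(v, lo, hi) {
  stopifnot(is(v, "Volume"))
  lo <- as.integer(lo); hi <- as.integer(hi)
  d <- dim(v@data)
  if (length(lo) != 3L || length(hi) != 3L ||
      any(lo < 0L) || any(hi > d) || any(lo >= hi)) {
    stop("crop box out of range: need 0 <= lo < hi <= extents per axis")
  }
  out <- v@data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                drop = FALSE]
  Volume(out, spacing = v@spacing, origin = v@origin + v@spacing * lo,
         dtypeTag = v@dtypeTag)
}

#' Bin a volume by block averaging
#'
#' Each output voxel is the arithmetic mean of a \code{factor^3} input
#' block (block-mean rather than decimation, to suppress noise before
#' registration). Trailing partial blocks are dropped rather than padded,
#' avoiding edge bias. The spacing is multiplied by the factor and the
#' origin moves to the centre of the first block.
#'
#' @param v a [Volume-class].
#' @param factor positive integer binning factor. Exactly one of
#'   \code{factor} and \code{targetSpacing} must be given.
#' @param targetSpacing target voxel spacing in um; the factor is then
#'   \code{round(targetSpacing / spacing(v))} and must be >= 1.
#' @return the binned [Volume-class] (dtype becomes \code{"float32"}
#'   unless the factor is 1).
#' @examples
#' v <- Volume(array(0:7, c(2, 2, 2)), spacing = 0.406)
#' voxelData(binVolume(v, factor = 2))  # mean of 0..7 = 3.5
#' @export
binVolume <- function(v, factor = NULL, targetSpacing = NULL) {
  stopifnot(is(v, "Volume"))
  if (is.null(factor) == is.null(targetSpacing)) {
    stop("give exactly one of factor and targetSpacing")
  }
  if (!is.null(targetSpacing)) {
    factor <- round(targetSpacing / v@spacing)
    if (factor < 1) {
      stop("targetSpacing is finer than the volume spacing (factor < 1)")
    }
  }
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(v)
  d <- dim(v@data)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("binning factor larger than a volume extent")
  x <- v@data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
              seq_len(nd[3] * factor), drop = FALSE]
  dim(x) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(factor^3, prod(nd))
  out <- array(colMeans(x), nd)
  Volume(out, spacing = v@spacing * factor,
         origin = v@origin + v@spacing * (factor - 1) / 2,
         dtypeTag = "float32")
}

#' Rescale a volume to 8-bit with percentile clipping
#'
#' Intensities at or below the low percentile map to 0, at or above the
#' high percentile to 255, linearly in between, rounded half-up (so
#' quantization is deterministic across platforms). Constant input maps
#' to all zeros. The default percentiles (0.5, 99.5) are robust: a single
#' hot voxel cannot flatten the contrast of the whole volume.
#'
#' @param v a [Volume-class].
#' @param pLo,pHi clipping percentiles, \code{0 <= pLo < pHi <= 100}.
#' @return a \code{"uint8"} [Volume-class] with values in 0..255.
#' @export
to8bit <- function(v, pLo = 0.5, pHi = 99.5) {
  stopifnot(is(v, "Volume"))
  if (!(pLo >= 0 && pLo < pHi && pHi <= 100)) {
    stop("need 0 <= pLo < pHi <= 100")
  }
  q <- stats::quantile(v@data, probs = c(pLo, pHi) / 100, names = FALSE)
  lo <- q[1]; hi <- q[2]
  if (hi <= lo) {
    out <- array(0, dim(v@data))
  } else {
    sc <- (v@data - lo) / (hi - lo) * 255
    out <- floor(pmin(pmax(sc, 0), 255) + 0.5)  # round half-up
  }
  Volume(out, spacing = v@spacing, origin = v@origin, dtypeTag = "uint8")
}

#' Sum fluorescence channels into a single 8-bit volume
#'
#' Sparse fluorescent labelling is low in structural content; summing all
#' channels into one dataset improves registration. The voxelwise sum is
#' accumulated in double precision and rescaled to 8-bit over its full
#' range (percentiles 0 and 100). A single channel is simply rescaled.
#'
#' @param mc a [MultiChannelVolume-class] (or a single [Volume-class]).
#' @return a \code{"uint8"} [Volume-class].
#' @export
sumChannels <- function(mc) {
  if (is(mc, "Volume")) mc <- MultiChannelVolume(list(mc))
  stopifnot(is(mc, "MultiChannelVolume"))
  acc <- mc@channels[[1L]]@data
  for (ch in mc@channels[-1L]) acc <- acc + ch@data
  v <- Volume(acc, spacing = spacing(mc), origin = origin(mc))
  to8bit(v, 0, 100)
}
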