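#' @import methods
NULL

#' Volume: a 3D scalar grid with isotropic voxel spacing
#'
#' The common currency of the pipeline. The data array is stored in
#' slice-major order: \code{data[i, j, k]} indexes (depth, row, column),
#' matching the page order of a TIFF stack. The world coordinate (in
#' micrometres) of the centre of voxel with zero-based index
#' \code{(i, j, k)} is \code{origin + spacing * c(i, j, k)}; this single
#' coordinate convention is used package-wide. Spacing is a strictly
#' positive isotropic scalar -- both instruments the pipeline targets
#' deliver isotropic voxels, and anisotropy is treated as an error rather
#' than a silent resample.
#'
#' @slot data numeric 3D array, axis order depth--row--column.
#' @slot spacing voxel edge length in micrometres (isotropic scalar).
#' @slot origin world position (um) of the centre of voxel (0, 0, 0).
#' @slot dtypeTag one of \code{"uint8"}, \code{"uint16"}, \code{"float32"};
#'   the on-disk sample format the data conform to.
#'
#' @seealso [Volume()], [readVolume()], [cropVolume()], [binVolume()]
#' @exportClass Volume
setClass("Volume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    dtypeTag = "character"
  ),
  prototype(
    data = array(0, c(1, 1, 1)),
    spacing = 1,
    origin = c(0, 0, 0),
    dtypeTag = "float32"
  )
)

setValidity("Volume", function(object) {
  msgs <- character()
  d <- object@data
  if (length(dim(d)) != 3L) {
    msgs <- c(msgs, "data must be a 3D array (depth, row, column)")
  } else if (any(dim(d) < 1L)) {
    msgs <- c(msgs, "all three grid extents must be >= 1")
  }
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0) {
    msgs <- c(msgs, "spacing must be a single positive finite number (um)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    msgs <- c(msgs, "origin must be a finite 3-vector (um)")
  }
  if (length(object@dtypeTag) != 1L ||
      !object@dtypeTag %in% c("uint8", "uint16", "float32")) {
    msgs <- c(msgs, "dtypeTag must be one of uint8, uint16, float32")
  }
  if (length(msgs)) msgs else TRUE
})

#' MultiChannelVolume: geometrically identical fluorescence channels
#'
#' An ordered list of [Volume] objects sharing grid shape, spacing and
#' origin, e.g. the fluorescence channels of one light-sheet acquisition.
#'
#' @slot channels list of [Volume] objects on an identical grid.
#' @slot names character channel labels, one per channel.
#'
#' @seealso [MultiChannelVolume()], [sumChannels()]
#' @exportClass MultiChannelVolume
setClass("MultiChannelVolume",
  representation(channels = "list", names = "character")
)

setValidity("MultiChannelVolume", function(object) {
  ch <- object@channels
  if (length(ch) < 1L) return("at least one channel is required")
  if (!all(vapply(ch, is, logical(1), class2 = "Volume"))) {
    return("all channels must be Volume objects")
  }
  if (length(object@names) != length(ch)) {
    return("one name per channel is required")
  }
  ref <- ch[[1L]]
  for (v in ch[-1L]) {
    if (!identical(dim(v@data), dim(ref@data)) ||
        abs(v@spacing - ref@spacing) > 1e-9 ||
        max(abs(v@origin - ref@origin)) > 1e-9) {
      return("all channels must share grid shape, spacing and origin")
    }
  }
  TRUE
})

#' SimilarityTransform: rotation + isotropic scale + translation
#'
#' A 4x4 homogeneous matrix acting on world coordinates (um), whose
#' linear part is \code{s * R} with \code{R} a proper rotation and
#' \code{s > 0} an isotropic scale. Similarity is the transform class
#' that absorbs specimen shrinkage between modalities: transforms map
#' moving-space world coordinates to fixed-space world coordinates.
#'
#' @slot matrix 4x4 homogeneous matrix; last row (0, 0, 0, 1).
#'
#' @seealso [similarityTransform()], [estimateSimilarity()],
#'   [scaleFactor()], [shrinkagePercent()]
#' @exportClass SimilarityTransform
setClass("SimilarityTransform", representation(matrix = "matrix"))

setValidity("SimilarityTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L))) {
    return("matrix must be a numeric 4x4 matrix")
  }
  if (any(!is.finite(m))) return("matrix must be finite")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    return("last row must be (0, 0, 0, 1)")
  }
  A <- m[1:3, 1:3]
  dt <- det(A)
  if (dt <= 0) return("linear part must have positive determinant (s^3 > 0)")
  s <- dt^(1 / 3)
  R <- A / s
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    return("linear part must be isotropic-scale times a proper rotation")
  }
  TRUE
})

#' DisplacementField: coarse lattice of residual displacement vectors
#'
#' A non-rigid residual correction living in fixed space: a coarse 3D
#' lattice of 3-vectors (um), interpolated trilinearly between nodes and
#' extended with the clamped edge value outside the lattice. As a
#' transform stage it maps a fixed-space point \code{x} to
#' \code{x + d(x)}; the all-zero field is the identity mapping.
#'
#' @slot vectors numeric 4D array, dim (n1, n2, n3, 3): the displacement
#'   vector stored at each lattice node, components in axis order.
#' @slot nodeSpacing lattice node spacing in micrometres.
#' @slot origin world position (um) of lattice node (0, 0, 0).
#'
#' @seealso [displacementField()], [refineDense()], [applyToPoints()]
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(vectors = "array", nodeSpacing = "numeric",
                 origin = "numeric")
)

setValidity("DisplacementField", function(object) {
  v <- object@vectors
  if (length(dim(v)) != 4L || dim(v)[4] != 3L) {
    return("vectors must be a 4D array with last extent 3")
  }
  if (any(!is.finite(v))) return("displacement vectors must be finite")
  if (length(object@nodeSpacing) != 1L || object@nodeSpacing <= 0 ||
      !is.finite(object@nodeSpacing)) {
    return("nodeSpacing must be a single positive number (um)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be a finite 3-vector (um)")
  }
  TRUE
})

#' CompositeTransform: ordered stages applied right-to-left
#'
#' An ordered list of [SimilarityTransform] and [DisplacementField]
#' stages. Like a matrix product, the mapping applies the last stage
#' first: \code{stages = list(W, A)} means "apply A, then W". The empty
#' list is the identity mapping. This is the single merged transform the
#' pipeline applies to full-precision data.
#'
#' @slot stages list of SimilarityTransform / DisplacementField stages.
#'
#' @seealso [composeTransforms()], [applyToPoints()], [resampleVolume()]
#' @exportClass CompositeTransform
setClass("CompositeTransform", representation(stages = "list"))

setValidity("CompositeTransform", function(object) {
  ok <- vapply(object@stages, function(s) {
    is(s, "SimilarityTransform") || is(s, "DisplacementField")
  }, logical(1))
  if (!all(ok)) {
    return("stages must be SimilarityTransform or DisplacementField objects")
  }
  TRUE
})

#' LandmarkSet: paired fixed/moving world points
#'
#' Equal-length lists of paired 3D world coordinates (um) picked in the
#' fixed (light-sheet) and moving (microCT) volumes -- e.g. eye lenses,
#' otoliths, the tail tip. At least 5 pairs are required for similarity
#' estimation.
#'
#' @slot fixedPoints n x 3 numeric matrix of fixed-space points (um).
#' @slot movingPoints n x 3 numeric matrix of moving-space points (um).
#' @slot labels optional landmark names (length n, may be empty).
#'
#' @seealso [landmarkSet()], [estimateSimilarity()],
#'   [targetRegistrationError()]
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(fixedPoints = "matrix", movingPoints = "matrix",
                 labels = "character")
)

setValidity("LandmarkSet", function(object) {
  f <- object@fixedPoints
  m <- object@movingPoints
  if (!is.numeric(f) || ncol(f) != 3L) return("fixedPoints must be n x 3")
  if (!is.numeric(m) || ncol(m) != 3L) return("movingPoints must be n x 3")
  if (nrow(f) != nrow(m)) {
    return("fixedPoints and movingPoints must have equal length")
  }
  if (any(!is.finite(f)) || any(!is.finite(m))) {
    return("landmark coordinates must be finite")
  }
  if (length(object@labels) && length(object@labels) != nrow(f)) {
    return("labels must be empty or one per pair")
  }
  TRUE
})

#' LabelVolume: integer tissue-segmentation grid
#'
#' An integer-valued grid aligned with a reference [Volume]; 0 is
#' background and every nonzero id present in the data must appear in the
#' lookup table (e.g. 1 = retina, 2 = brain, 3 = lens).
#'
#' @slot data integer 3D array (depth, row, column).
#' @slot table named integer vector mapping tissue name -> label id.
#' @slot spacing voxel spacing (um), matching the reference grid.
#' @slot origin world position (um) of voxel (0, 0, 0).
#'
#' @seealso [labelVolume()], [markerFraction()], [tissueVolumes()]
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", table = "integer", spacing = "numeric",
                 origin = "numeric")
)

setValidity("LabelVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(d < 0)) return("labels must be non-negative integers")
  if (any(d != round(d))) return("labels must be integer-valued")
  ids <- sort(unique(as.vector(d)))
  ids <- ids[ids != 0]
  if (!all(ids %in% object@table)) {
    return("every nonzero label id must be present in the table")
  }
  if (is.null(names(object@table)) && length(object@table)) {
    return("table must be a named integer vector (tissue name -> id)")
  }
  if (length(object@spacing) != 1L || object@spacing <= 0) {
    return("spacing must be a single positive number (um)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be a finite 3-vector (um)")
  }
  TRUE
})

#' BlockMatchParams: tuning of the block-matching refinement
#'
#' @slot blockSize voxels per block side (default 8).
#' @slot blockStride stride between block starts, voxels (default 8).
#' @slot searchRadius exhaustive integer search radius, voxels (default 4).
#' @slot iterations block-match / fit rounds per pyramid level (default 20,
#'   the number of iterations used for this stage in practice).
#' @slot varianceFloor minimum fixed-block intensity variance for
#'   eligibility; \code{NA} selects the 10th percentile of block variances.
#' @slot trimFraction fraction of worst correspondences discarded in the
#'   robust similarity fit (default 0.25).
#' @slot pyramidLevels multiresolution levels, each binning by 2 (default 3).
#'
#' @seealso [blockMatchParams()], [registerSimilarity()]
#' @exportClass BlockMatchParams
setClass("BlockMatchParams",
  representation(blockSize = "integer", blockStride = "integer",
                 searchRadius = "integer", iterations = "integer",
                 varianceFloor = "numeric", trimFraction = "numeric",
                 pyramidLevels = "integer")
)

setValidity("BlockMatchParams", function(object) {
  msgs <- character()
  if (object@blockSize < 3L) msgs <- c(msgs, "blockSize must be >= 3")
  if (object@blockStride < 1L) msgs <- c(msgs, "blockStride must be >= 1")
  if (object@searchRadius < 1L) msgs <- c(msgs, "searchRadius must be >= 1")
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (object@trimFraction < 0 || object@trimFraction >= 0.5) {
    msgs <- c(msgs, "trimFraction must be in [0, 0.5)")
  }
  if (object@pyramidLevels < 1L) msgs <- c(msgs, "pyramidLevels must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' RegistrationReport: quantitative registration quality record
#'
#' @slot rmsLandmarkResidual RMS residual (um) of the landmark fit.
#' @slot treHeldout mean target registration error (um) over landmarks
#'   excluded from fitting; \code{NA} when no held-out set was supplied.
#' @slot perIterationResiduals list (one element per pyramid level) of
#'   mean correspondence displacements per iteration, in level voxels.
#' @slot shrinkage linear specimen shrinkage (percent) implied by the
#'   fitted similarity.
#' @slot warnings character vector of diagnostics raised during the run.
#'
#' @seealso [registerSimilarity()], [targetRegistrationError()],
#'   [shrinkagePercent()]
#' @exportClass RegistrationReport
setClass("RegistrationReport",
  representation(rmsLandmarkResidual = "numeric", treHeldout = "numeric",
                 perIterationResiduals = "list", shrinkage = "numeric",
                 warnings = "character")
)

setValidity("RegistrationReport", function(object) {
  if (length(object@rmsLandmarkResidual) == 1L &&
      is.finite(object@rmsLandmarkResidual) &&
      object@rmsLandmarkResidual < 0) {
    return("residuals must be >= 0")
  }
  TRUE
})

#' PhantomSpec: conditions of a synthetic paired-modality specimen
#'
#' Defines a blob-textured specimen imaged twice with differing contrast:
#' a multi-channel fluorescence rendering on a fine grid and a dense
#' histology-like rendering on a 3x coarser grid, related by a global
#' similarity (including uniform shrinkage), an optional smooth residual
#' warp, and additive Gaussian noise. The seed fully determines all
#' outputs.
#'
#' @slot dims fluorescence (fixed) grid extents, voxels.
#' @slot spimSpacing fluorescence voxel spacing, um (default 0.406).
#' @slot ctSpacing tomography voxel spacing, um (default 1.22).
#' @slot nNuclei number of nuclei placed inside the tissues.
#' @slot nucleusRadius nucleus blob radius, um.
#' @slot tissues list of ellipsoids: each \code{list(label, name, center,
#'   semiaxes)} with center/semiaxes in um, fixed space; later entries
#'   override earlier ones in the label volume.
#' @slot markerMaps list per channel: \code{list(name, tissues, prob)} --
#'   the label ids expressing the marker and the per-nucleus expression
#'   probability.
#' @slot shrinkageScale tomography scale relative to fluorescence, in
#'   (0, 1]; models dehydration shrinkage (default 0.795, i.e. 20.5
#'   percent linear shrinkage).
#' @slot rotationAxis,rotationAngle axis (3-vector) and angle (degrees)
#'   of the true rotation.
#' @slot translation true translation, um (moving space).
#' @slot warpAmplitude peak amplitude (um) of the smooth residual warp;
#'   0 disables it.
#' @slot nWarpComponents number of low-frequency sinusoidal warp
#'   components (at most 3).
#' @slot noiseSigmaSpim,noiseSigmaCt additive Gaussian noise sd per
#'   modality, intensity units (nucleus peak is 100).
#' @slot seed integer seed; fully determines all outputs.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(dims = "integer", spimSpacing = "numeric",
                 ctSpacing = "numeric", nNuclei = "integer",
                 nucleusRadius = "numeric", tissues = "list",
                 markerMaps = "list", shrinkageScale = "numeric",
                 rotationAxis = "numeric", rotationAngle = "numeric",
                 translation = "numeric", warpAmplitude = "numeric",
                 nWarpComponents = "integer", noiseSigmaSpim = "numeric",
                 noiseSigmaCt = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@dims) != 3L || any(object@dims < 8L)) {
    msgs <- c(msgs, "dims must be three extents >= 8")
  }
  if (object@shrinkageScale <= 0 || object@shrinkageScale > 1) {
    msgs <- c(msgs, "shrinkageScale must be in (0, 1]")
  }
  if (object@nWarpComponents > 3L) {
    msgs <- c(msgs, "at most 3 warp components (band-limited warp)")
  }
  if (object@warpAmplitude < 0) msgs <- c(msgs, "warpAmplitude must be >= 0")
  if (length(msgs)) msgs else TRUE
})
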