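#' Voxel spacing of a gridded object
#'
#' @param x a [Volume], [LabelVolume], [MultiChannelVolume] or
#'   [DisplacementField].
#' @return voxel (or lattice node) spacing in micrometres.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' World origin of a gridded object
#'
#' @param x a gridded object.
#' @return world position (um) of the centre of voxel (0, 0, 0).
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Raw data array of a gridded object
#'
#' @param x a [Volume] or [LabelVolume].
#' @return the underlying 3D array (depth, row, column).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Grid extents of a gridded object
#'
#' @param x a gridded object.
#' @return integer 3-vector of extents (depth, row, column).
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Map a transform over 3D points
#'
#' Applies a transform to world-coordinate points (um). For a
#' [CompositeTransform] the stages are applied right-to-left (last stage
#' first); a [DisplacementField] stage adds the trilinear interpolation
#' of its node vectors to each point.
#'
#' @param transform a [SimilarityTransform], [DisplacementField] or
#'   [CompositeTransform].
#' @param points n x 3 numeric matrix of world coordinates (um).
#' @return n x 3 matrix of mapped points.
#' @export
setGeneric("applyToPoints",
           function(transform, points) standardGeneric("applyToPoints"))

#' Map points through the inverse of a transform
#'
#' Similarity stages are inverted exactly; displacement-field stages are
#' inverted by fixed-point iteration (at most \code{maxIter} sweeps,
#' stopping when the largest update falls below \code{tol} um). If the
#' iteration does not converge a warning is raised and the last iterate
#' is used.
#'
#' @param transform a [SimilarityTransform], [DisplacementField] or
#'   [CompositeTransform].
#' @param points n x 3 numeric matrix of world coordinates (um).
#' @param tol convergence tolerance in um.
#' @param maxIter maximum fixed-point iterations per field stage.
#' @return n x 3 matrix of pre-images, with attribute
#'   \code{"converged"} (logical).
#' @export
setGeneric("invertPoints",
           function(transform, points, tol = 1e-6, maxIter = 20L)
             standardGeneric("invertPoints"))
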