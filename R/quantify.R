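#' Construct a LabelVolume
#'
#' @param data integer 3D array (0 = background).
#' @param table named integer vector mapping tissue name to label id,
#'   e.g. \code{c(retina = 1L, brain = 2L, lens = 3L)}.
#' @param spacing voxel spacing (um) of the aligned reference grid.
#' @param origin world origin (um).
#' @return a [LabelVolume-class].
#' @export
labelVolume <- function(data, table, spacing, origin = c(0, 0, 0)) {
  tab <- as.integer(table)
  names(tab) <- names(table)
  new("LabelVolume", data = array(as.integer(data), dim(data)),
      table = tab, spacing = as.double(spacing),
      origin = as.double(origin))
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %d x %d x %d, spacing %.6f um, %d tissue(s)\n",
              d[1], d[2], d[3], object@spacing, length(object@table)))
  for (i in seq_along(object@table)) {
    cat(sprintf("  %s = %d\n", names(object@table)[i], object@table[i]))
  }
})

#' Tissue lookup table of a LabelVolume
#' @param x a [LabelVolume-class].
#' @return named integer vector (tissue name -> label id).
#' @export
labelTable <- function(x) x@table

#' Otsu threshold of an intensity sample
#'
#' Builds a 256-bin histogram over \code{[min, max]} of the sample and
#' exhaustively searches the inter-bin cut maximising the between-class
#' variance \eqn{w_0 w_1 (\mu_0 - \mu_1)^2}; ties take the lowest cut.
#' The returned threshold is the intensity at the cut's upper bin edge,
#' and mask membership is defined by the strict inequality
#' \code{value > threshold} (documented so that voxel counts are
#' reproducible bit-exactly).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold intensity.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(255, 50)))  # cut right above the low mode
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  mn <- min(values); mx <- max(values)
  if (!(mx > mn)) stop("degenerate histogram: constant input")
  width <- (mx - mn) / nbins
  idx <- pmin(floor((values - mn) / width) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  mids <- mn + (seq_len(nbins) - 0.5) * width
  N <- length(values)
  cumN <- cumsum(counts)
  cumS <- cumsum(counts * mids)
  t <- seq_len(nbins - 1L)
  n0 <- cumN[t]; n1 <- N - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- cumS[t] / n0
  mu1 <- (cumS[nbins] - cumS[t]) / n1
  bc <- (n0 / N) * (n1 / N) * (mu0 - mu1)^2
  bc[!valid] <- -Inf
  cut <- which.max(bc)  # first maximum = lowest cut on ties
  mn + cut * width
}

#' Per-tissue marker fraction within combined labels
#'
#' Reproduces the marker-quantification rule of the downstream analysis:
#' the Otsu threshold is computed per channel over the voxels whose
#' label belongs to \code{combineIds} (e.g. the combined retina and
#' brain labels -- voxels outside the combined region never enter the
#' histogram), the mask \code{channel > threshold} is intersected with
#' the single tissue of interest, and the count is normalised by that
#' tissue's voxel count, giving a dimensionless fraction.
#'
#' @param channel a [Volume-class] fluorescence channel.
#' @param labels a [LabelVolume-class] on the same grid.
#' @param combineIds label ids pooled for threshold estimation.
#' @param tissueId the tissue (must be in \code{combineIds}) whose
#'   fraction is reported.
#' @param channelName channel label for the output record.
#' @return one-row data frame: tissue, channel, threshold,
#'   marker_voxels, tissue_voxels, fraction, volume_um3.
#' @export
markerFraction <- function(channel, labels, combineIds, tissueId,
                           channelName = "channel") {
  stopifnot(is(channel, "Volume"), is(labels, "LabelVolume"))
  if (!identical(dim(channel@data), dim(labels@data)) ||
      abs(channel@spacing - labels@spacing) > 1e-9) {
    stop("channel and labels must be on the same grid")
  }
  if (!tissueId %in% combineIds) stop("tissueId must be in combineIds")
  region <- labels@data %in% combineIds
  if (!any(region)) stop("combined label region is empty")
  tissue <- labels@data == tissueId
  tv <- sum(tissue)
  if (tv == 0L) stop("empty tissue: no voxels with label ", tissueId)
  thr <- otsuThreshold(channel@data[region])
  mv <- sum(channel@data > thr & tissue)
  nm <- names(labels@table)[match(tissueId, labels@table)]
  if (is.na(nm)) nm <- as.character(tissueId)
  data.frame(tissue = nm, channel = channelName, threshold = thr,
             marker_voxels = mv, tissue_voxels = tv,
             fraction = mv / tv,
             volume_um3 = tv * labels@spacing^3)
}

#' Per-tissue voxel counts and volumes
#'
#' @param labels a [LabelVolume-class].
#' @return data frame with one row per label present in the volume:
#'   tissue, label, voxels, volume_um3 (\code{voxels * spacing^3}).
#'   Labels absent from the data are omitted.
#' @export
tissueVolumes <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  ids <- sort(unique(as.vector(labels@data)))
  ids <- ids[ids != 0]
  if (length(ids) == 0L) {
    return(data.frame(tissue = character(), label = integer(),
                      voxels = integer(), volume_um3 = numeric()))
  }
  counts <- vapply(ids, function(i) sum(labels@data == i), numeric(1))
  nm <- names(labels@table)[match(ids, labels@table)]
  nm[is.na(nm)] <- as.character(ids[is.na(nm)])
  data.frame(tissue = nm, label = as.integer(ids),
             voxels = as.integer(counts),
             volume_um3 = counts * labels@spacing^3)
}

#' Linear specimen shrinkage implied by a similarity transform
#'
#' With the transform mapping the tomography (moving) volume to the
#' light-sheet (fixed) volume, a scale factor \code{s > 1} means the
#' stained specimen is smaller than its fluorescence image. Linear
#' shrinkage is \code{(1 - 1/s) * 100} percent -- equivalently
#' \code{(1 - s') * 100} with \code{s' = 1/s} the tomography-relative
#' scale. Shrinkage is defined on the linear scale factor (not
#' volumetric); the scale factor is exposed via [scaleFactor()] so either
#' convention can be recomputed.
#'
#' @param t a [SimilarityTransform-class] mapping moving (tomography) to
#'   fixed (light-sheet) coordinates.
#' @return linear shrinkage in percent (0 for the identity).
#' @examples
#' shrinkagePercent(similarityTransform())            # 0
#' shrinkagePercent(similarityFromComponents(1/0.795))  # 20.5
#' @export
shrinkagePercent <- function(t) {
  stopifnot(is(t, "SimilarityTransform"))
  (1 - 1 / scaleFactor(t)) * 100
}

#' Tabulate marker quantifications across phenotype groups
#'
#' Collates per-specimen [markerFraction()] records into a per-group
#' summary and a long-format plot table. No hypothesis test is applied:
#' the comparison this supports is typically n = 1 specimen per
#' phenotype, and fabricating inference would misrepresent the data.
#'
#' @param quantifications list of data frames from [markerFraction()]
#'   (or one combined data frame).
#' @param grouping phenotype label per record (recycled across the rows
#'   of each element).
#' @return list with \code{table} (group x tissue x channel rows with
#'   fraction and tissue volume) and \code{plotData} (long format:
#'   group, tissue, channel, metric, value).
#' @export
compareGroups <- function(quantifications, grouping) {
  if (is.data.frame(quantifications)) quantifications <- list(quantifications)
  if (length(grouping) != length(quantifications)) {
    stop("one grouping label per quantification record is required")
  }
  rows <- Map(function(df, g) cbind(group = g, df),
              quantifications, grouping)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  long <- rbind(
    data.frame(group = tab$group, tissue = tab$tissue,
               channel = tab$channel, metric = "fraction",
               value = tab$fraction),
    data.frame(group = tab$group, tissue = tab$tissue,
               channel = tab$channel, metric = "volume_um3",
               value = tab$volume_um3))
  list(table = tab, plotData = long)
}
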