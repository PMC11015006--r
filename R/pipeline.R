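## Workflow commands tying the stages into the three-part pipeline:
## compress -> register -> apply/quantify, plus phantom simulation and
## checkerboard QC. Each command takes a config (YAML path or list),
## writes its outputs under config$output_dir and echoes the full config
## there for provenance. A thin shell dispatcher for these commands is
## installed at inst/scripts/voxalign.

#' Read a run configuration
#'
#' @param config a YAML file path or a named list.
#' @return a named list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.prepareOutDir <- function(config, what) {
  outDir <- config$output_dir
  if (is.null(outDir)) stop(what, ": config needs output_dir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir,
                                     paste0(what, "_config.yaml")))
  outDir
}

#' Simulate a phantom dataset on disk
#'
#' Writes the fluorescence channels (TIFF stacks + spacing sidecars),
#' the tomography volume and labels (NRRD), the landmark files and a
#' \code{truth.json} echoing the spec, the true transform and the true
#' shrinkage. Reruns with the same config are byte-identical.
#'
#' @param config YAML path or list with \code{output_dir}, \code{seed}
#'   and optional overrides of [phantomSpec()] arguments
#'   (\code{dims}, \code{shrinkage_scale}, \code{rotation_angle},
#'   \code{translation}, \code{warp_amplitude}, \code{n_nuclei}).
#' @return (invisibly) the phantom list from [generatePhantom()].
#' @export
runSimulate <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "simulate")
  spec <- phantomSpec(
    dims = if (!is.null(config$dims)) unlist(config$dims) else c(96L, 96L, 96L),
    seed = if (!is.null(config$seed)) config$seed else 1L,
    shrinkageScale = config$shrinkage_scale %||% 0.795,
    rotationAngle = config$rotation_angle %||% 5,
    translation = unlist(config$translation %||% c(0, 0, 0)),
    warpAmplitude = config$warp_amplitude %||% 3,
    nNuclei = config$n_nuclei %||% 400L)
  ph <- generatePhantom(spec)
  chans <- channels(ph$spim)
  for (nm in names(chans)) {
    writeVolume(chans[[nm]], file.path(outDir, paste0("spim_", nm, ".tif")))
  }
  writeVolume(ph$ct, file.path(outDir, "ct.nrrd"))
  .writeNRRD(ph$labels@data, file.path(outDir, "labels.nrrd"),
             dtype = "uint16", spacing = ph$labels@spacing,
             origin = ph$labels@origin)
  writeLandmarks(ph$truth$landmarks, file.path(outDir, "landmarks.csv"))
  writeLandmarks(ph$truth$heldout, file.path(outDir, "landmarks_heldout.csv"))
  writeTransform(ph$truth$composite, file.path(outDir, "truth_transform.json"))
  jsonlite::write_json(
    list(seed = spec@seed, dims = spec@dims,
         spim_spacing_um = spec@spimSpacing,
         ct_spacing_um = spec@ctSpacing,
         shrinkage_percent = ph$truth$shrinkagePercent,
         n_landmarks = nrow(ph$truth$landmarks@fixedPoints),
         label_table = as.list(ph$labels@table)),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compression stage: crop, bin, 8-bit conversion, channel summation
#'
#' Applies the staged compression of the pipeline to both modalities:
#' optional crop, block-mean binning of the fluorescence channels to the
#' tomography spacing, 8-bit percentile rescaling, and channel summation
#' into the single fixed volume used for registration. Writes a byte
#' size report.
#'
#' @param config YAML path or list with \code{spim_channels} (paths),
#'   \code{ct} (path), \code{output_dir}; optional \code{crop_lo} /
#'   \code{crop_hi} (zero-based, applied to the CT volume),
#'   \code{target_spacing_um} (default: the CT spacing),
#'   \code{percentiles} (default c(0.5, 99.5)).
#' @return (invisibly) list with \code{fixed} and \code{moving} 8-bit
#'   volumes and the size report data frame.
#' @export
runCompress <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "compress")
  pcts <- unlist(config$percentiles %||% c(0.5, 99.5))
  ct <- readVolume(config$ct)
  if (!is.null(config$crop_lo)) {
    ct <- cropVolume(ct, unlist(config$crop_lo), unlist(config$crop_hi))
  }
  ct8 <- to8bit(ct, pcts[1], pcts[2])
  target <- config$target_spacing_um %||% ct@spacing
  chans <- lapply(config$spim_channels, readVolume)
  binned <- lapply(chans, binVolume, targetSpacing = target)
  fixed <- sumChannels(MultiChannelVolume(binned))
  writeVolume(ct8, file.path(outDir, "ct_8bit.nrrd"))
  writeVolume(fixed, file.path(outDir, "spim_summed_8bit.nrrd"))
  inPaths <- c(unlist(config$spim_channels), config$ct)
  outPaths <- file.path(outDir, c("spim_summed_8bit.nrrd", "ct_8bit.nrrd"))
  report <- data.frame(
    file = c(inPaths, outPaths),
    role = c(rep("input", length(inPaths)), rep("output", 2L)),
    bytes = file.size(c(inPaths, outPaths)))
  utils::write.csv(report, file.path(outDir, "size_report.csv"),
                   row.names = FALSE)
  invisible(list(fixed = fixed, moving = ct8, report = report))
}

#' Registration stage: landmarks, block matching, dense field
#'
#' Runs the registration chain: similarity estimated from the landmark
#' file, block-matching refinement over the pyramid, one dense
#' displacement-field pass, and the merge of all stages into a single
#' composite transform, serialized as JSON. Also writes a registration
#' report (landmark RMS, per-iteration residuals, shrinkage, held-out
#' TRE when a held-out landmark file is given).
#'
#' @param config YAML path or list with \code{fixed} and \code{moving}
#'   (compressed 8-bit volume paths), \code{landmarks} (CSV),
#'   \code{output_dir}; optional \code{landmarks_heldout},
#'   \code{block_size}, \code{search_radius}, \code{iterations},
#'   \code{pyramid_levels}, \code{trim_fraction},
#'   \code{dense_field} (logical, default TRUE).
#' @return (invisibly) list with \code{transform}
#'   ([CompositeTransform-class]) and \code{report}
#'   ([RegistrationReport-class]).
#' @export
runRegister <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "register")
  fixed <- readVolume(config$fixed)
  moving <- readVolume(config$moving)
  if (is.null(config$landmarks)) {
    stop("no landmark file given (config$landmarks); landmark ",
         "initialisation is required")
  }
  lm <- readLandmarks(config$landmarks)
  params <- blockMatchParams(
    blockSize = config$block_size %||% 8L,
    blockStride = config$block_stride %||% 8L,
    searchRadius = config$search_radius %||% 4L,
    iterations = config$iterations %||% 20L,
    trimFraction = config$trim_fraction %||% 0.25,
    pyramidLevels = config$pyramid_levels %||% 3L)
  warnings <- character()
  init <- estimateSimilarity(lm)
  reg <- registerSimilarity(fixed, moving, init$transform, params)
  stages <- list(reg$transform)
  if (isTRUE(config$dense_field %||% TRUE)) {
    movReg <- resampleVolume(moving, reg$transform, fixed, "linear")
    field <- refineDense(fixed, movReg, params)
    stages <- c(list(field), stages)
  }
  merged <- composeTransforms(stages)
  writeTransform(merged, file.path(outDir, "transform.json"))
  tre <- NA_real_
  if (!is.null(config$landmarks_heldout)) {
    ho <- readLandmarks(config$landmarks_heldout)
    tre <- targetRegistrationError(merged, ho)$mean
  }
  report <- registrationReport(
    rmsLandmarkResidual = init$rmsResidual,
    treHeldout = tre,
    perIterationResiduals = reg$residuals,
    shrinkage = shrinkagePercent(reg$transform),
    warnings = warnings)
  jsonlite::write_json(
    list(rms_landmark_residual_um = report@rmsLandmarkResidual,
         tre_heldout_um = report@treHeldout,
         shrinkage_percent = report@shrinkage,
         per_iteration_residuals_vox = report@perIterationResiduals,
         converged = reg$converged,
         pyramid_factors = reg$levels),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(transform = merged, report = report))
}

#' Apply the merged transform to full-precision data
#'
#' Resamples the original (uncompressed) moving volume onto the fixed
#' reference grid through the merged transform -- linear interpolation
#' for intensities, nearest for label volumes.
#'
#' @param config YAML path or list with \code{moving} (original
#'   full-precision volume path), \code{transform} (JSON path from
#'   [runRegister()]), \code{reference} (volume path defining the output
#'   grid), \code{output_dir}; optional \code{interpolation}
#'   (\code{"linear"}/\code{"nearest"}).
#' @return (invisibly) the resampled [Volume-class].
#' @export
runApply <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "apply")
  moving <- readVolume(config$moving)
  reference <- readVolume(config$reference)
  transform <- readTransform(config$transform)
  out <- resampleVolume(moving, transform, reference,
                        config$interpolation %||% "linear")
  writeVolume(out, file.path(outDir, "registered.nrrd"))
  invisible(out)
}

#' Quantification stage: Otsu marker fractions per tissue
#'
#' For every channel, computes the Otsu threshold over the combined
#' label region and the marker fraction of each requested tissue, and
#' writes the quantification CSV (tissue, channel, threshold,
#' marker_voxels, tissue_voxels, fraction, volume_um3) plus a tissue
#' volume table. If ggplot2 is installed a bar chart of fractions is
#' written alongside.
#'
#' @param config YAML path or list with \code{spim_channels} (paths),
#'   \code{labels} (NRRD path), \code{output_dir}; optional
#'   \code{combine_ids} (default: all nonzero labels),
#'   \code{tissue_ids} (default: \code{combine_ids}),
#'   \code{label_table} (named list tissue -> id),
#'   \code{channel_names}.
#' @return (invisibly) the quantification data frame.
#' @export
runQuantify <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "quantify")
  labRaw <- readVolume(config$labels)
  tabList <- config$label_table %||% list()
  ids <- sort(unique(as.vector(labRaw@data)))
  ids <- ids[ids != 0]
  tab <- if (length(tabList)) {
    stats::setNames(as.integer(unlist(tabList)), names(tabList))
  } else {
    stats::setNames(as.integer(ids), paste0("tissue", ids))
  }
  labels <- labelVolume(labRaw@data, tab, spacing = labRaw@spacing,
                        origin = labRaw@origin)
  combineIds <- as.integer(unlist(config$combine_ids %||% ids))
  tissueIds <- as.integer(unlist(config$tissue_ids %||% combineIds))
  bad <- setdiff(tissueIds, ids)
  if (length(bad)) {
    stop("label id(s) absent from the label volume: ",
         paste(bad, collapse = ", "))
  }
  chanPaths <- unlist(config$spim_channels)
  chanNames <- unlist(config$channel_names %||%
                        tools::file_path_sans_ext(basename(chanPaths)))
  rows <- list()
  for (i in seq_along(chanPaths)) {
    ch <- readVolume(chanPaths[i])
    for (tid in tissueIds) {
      rows[[length(rows) + 1L]] <-
        markerFraction(ch, labels, combineIds, tid, chanNames[i])
    }
  }
  quant <- do.call(rbind, rows)
  utils::write.csv(quant, file.path(outDir, "quantification.csv"),
                   row.names = FALSE)
  utils::write.csv(tissueVolumes(labels),
                   file.path(outDir, "tissue_volumes.csv"),
                   row.names = FALSE)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(quant,
                         ggplot2::aes(x = .data$tissue, y = .data$fraction,
                                      fill = .data$channel)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "marker fraction of tissue volume", x = NULL)
    ggplot2::ggsave(file.path(outDir, "marker_fractions.png"), p,
                    width = 6, height = 4, dpi = 150)
  }
  invisible(quant)
}

#' Checkerboard QC sections
#'
#' Writes checkerboard composites of the fixed and registered moving
#' volumes on the three orthogonal mid-plane sections (axial, coronal,
#' sagittal), as PNG when the png package is available, otherwise as
#' ASCII NRRD matrices.
#'
#' @param config YAML path or list with \code{fixed} and
#'   \code{registered} (volume paths on the same grid),
#'   \code{output_dir}; optional \code{tile} (voxels, default 32).
#' @return (invisibly) list of the three checkerboard matrices.
#' @export
runCheckerboard <- function(config) {
  config <- readRunConfig(config)
  outDir <- .prepareOutDir(config, "checkerboard")
  fixed <- readVolume(config$fixed)
  moving <- readVolume(config$registered)
  tile <- config$tile %||% 32L
  out <- list()
  axNames <- c("axial", "coronal", "sagittal")
  for (ax in 1:3) {
    cb <- checkerboard(fixed, moving, tile = tile, sliceAxis = ax)
    out[[axNames[ax]]] <- cb
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(cb / 255, file.path(outDir,
                                        paste0("checkerboard_",
                                               axNames[ax], ".png")))
    } else {
      .writeNRRD(array(cb, c(dim(cb), 1L)),
                 file.path(outDir, paste0("checkerboard_", axNames[ax],
                                          ".nrrd")),
                 dtype = "uint8", spacing = fixed@spacing,
                 origin = c(0, 0, 0), encoding = "ascii")
    }
  }
  invisible(out)
}
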