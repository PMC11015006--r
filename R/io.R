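## Volume I/O: TIFF stacks (pages = slices) via the tiff package, and a
## minimal NRRD0004 reader/writer (raw + ascii encodings, little-endian).
## TIFF files carry no reliable spacing, so a YAML sidecar `<path>.yaml`
## stores spacing/origin/dtype; spacing is never silently assumed.

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff_stack")
  if (ext %in% c("nrrd", "nhdr")) return("nrrd")
  stop("cannot infer volume format from extension: ", path)
}

.sidecarPath <- function(path) paste0(path, ".yaml")

#' Read a 3D volume from disk
#'
#' Supported formats: multi-page TIFF stacks (one page per slice) and
#' NRRD. For TIFF, the voxel spacing comes from the YAML sidecar written
#' by [writeVolume()] (or from the \code{spacing} argument); a missing or
#' ambiguous spacing is an error, never silently assumed to be 1. NRRD
#' headers with anisotropic spacings are rejected, since the pipeline's
#' coordinate convention is isotropic.
#'
#' @param path file path.
#' @param format \code{"auto"} (from the extension), \code{"tiff_stack"}
#'   or \code{"nrrd"}.
#' @param spacing optional isotropic voxel spacing (um), overriding any
#'   sidecar.
#' @param origin optional world origin (um), overriding any sidecar.
#' @return a [Volume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "tiff_stack", "nrrd"),
                       spacing = NULL, origin = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1L]])) != 2L) {
      stop("dimensionality error: TIFF pages must be single-channel 2D")
    }
    data <- aperm(simplify2array(pages), c(3, 1, 2))
    meta <- list()
    if (file.exists(.sidecarPath(path))) {
      meta <- yaml::read_yaml(.sidecarPath(path))
    }
    if (is.null(spacing)) spacing <- meta$spacing_um
    if (is.null(spacing)) {
      stop("missing spacing for TIFF volume ", path,
           ": supply spacing= or a ", basename(.sidecarPath(path)),
           " sidecar (spacing is never assumed to be 1.0)")
    }
    if (is.null(origin)) origin <- meta$origin_um
    if (is.null(origin)) origin <- c(0, 0, 0)
    dtype <- meta$dtype
    if (is.null(dtype)) {
      dtype <- if (max(data) <= 255 && min(data) >= 0 &&
                   all(data == round(data))) "uint8" else "uint16"
    }
    Volume(data, spacing = spacing, origin = unlist(origin),
           dtypeTag = dtype)
  } else {
    nr <- .readNRRD(path)
    if (length(nr$sizes) != 3L) {
      stop("dimensionality error: expected a 3D NRRD, got ",
           length(nr$sizes), "D")
    }
    sp <- nr$spacings
    if (!is.null(spacing)) sp <- rep(spacing, 3)
    if (is.null(sp)) stop("missing spacing in NRRD header: ", path)
    if (max(sp) - min(sp) > 1e-9 * max(sp)) {
      stop("isotropic spacing required, got (",
           paste(format(sp), collapse = ", "), ")")
    }
    og <- if (!is.null(origin)) origin else nr$origin
    if (is.null(og)) og <- c(0, 0, 0)
    Volume(array(nr$data, nr$sizes), spacing = sp[1], origin = og,
           dtypeTag = nr$dtype)
  }
}

#' Write a 3D volume to disk
#'
#' TIFF stacks store \code{uint8}/\code{uint16} data bit-exactly (one
#' page per slice) together with a YAML sidecar holding spacing, origin
#' and dtype (um values at 6-decimal precision); \code{float32} data must
#' go to NRRD, which stores all three sample formats. Round-tripping
#' through [readVolume()] reproduces the data bit-exactly and the
#' spacing to 6 decimals.
#'
#' @param v a [Volume-class].
#' @param path destination path (.tif/.tiff or .nrrd).
#' @param format \code{"auto"}, \code{"tiff_stack"} or \code{"nrrd"}.
#' @param encoding NRRD encoding: \code{"raw"} (little-endian) or
#'   \code{"ascii"} (plain text, useful for small fixtures).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path, format = c("auto", "tiff_stack", "nrrd"),
                        encoding = c("raw", "ascii")) {
  stopifnot(is(v, "Volume"))
  format <- match.arg(format)
  encoding <- match.arg(encoding)
  if (format == "auto") format <- .guessFormat(path)
  if (format == "tiff_stack") {
    if (v@dtypeTag == "float32") {
      stop("float32 TIFF storage is not supported; write NRRD instead")
    }
    bits <- if (v@dtypeTag == "uint8") 8L else 16L
    mx <- 2^bits - 1
    if (any(v@data < 0) || any(v@data > mx) || any(v@data != round(v@data))) {
      stop("data do not conform to ", v@dtypeTag)
    }
    d <- dim(v@data)
    pages <- lapply(seq_len(d[1]), function(i) {
      matrix(v@data[i, , ], d[2], d[3]) / mx
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    yaml::write_yaml(list(spacing_um = as.numeric(sprintf("%.6f", v@spacing)),
                          origin_um = as.numeric(sprintf("%.6f", v@origin)),
                          dtype = v@dtypeTag),
                     .sidecarPath(path))
  } else {
    .writeNRRD(v@data, path, dtype = v@dtypeTag, spacing = v@spacing,
               origin = v@origin, encoding = encoding)
  }
  invisible(path)
}

## ---- minimal NRRD0004 support ------------------------------------------

.nrrdType <- function(dtype) {
  switch(dtype,
         uint8 = "uint8", uint16 = "uint16", float32 = "float",
         stop("unsupported dtype: ", dtype))
}

.writeNRRD <- function(data, path, dtype, spacing, origin,
                       encoding = "raw") {
  sizes <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# produced by voxalign",
    paste0("type: ", .nrrdType(dtype)),
    paste0("dimension: ", length(sizes)),
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("spacings: ", paste(sprintf("%.6f", rep(spacing, length(sizes))),
                               collapse = " ")),
    paste0("axis mins: ", paste(sprintf("%.6f", origin), collapse = " ")),
    paste0("encoding: ", encoding),
    if (encoding == "raw") "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  x <- as.vector(data)
  if (encoding == "ascii") {
    txt <- if (dtype == "float32") {
      sprintf("%.9g", x)
    } else {
      sprintf("%d", as.integer(x))
    }
    writeLines(paste(txt, collapse = " "), con, sep = "\n")
  } else {
    if (dtype == "uint8") {
      writeBin(as.raw(as.integer(x)), con)
    } else if (dtype == "uint16") {
      xi <- as.integer(x)
      bytes <- rbind(xi %% 256L, xi %/% 256L)
      writeBin(as.raw(bytes), con)
    } else {
      writeBin(x, con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

.readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated NRRD header: ", path)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+:", line))
    key <- tolower(trimws(sub(":$", "", kv)))
    val <- trimws(sub("^[^:]+:[ ]?", "", line))
    fields[[key]] <- val
  }
  sizes <- as.integer(strsplit(fields$sizes, "[ \t]+")[[1L]])
  n <- prod(sizes)
  type <- fields$type
  dtype <- switch(type,
                  uint8 = "uint8", `unsigned char` = "uint8",
                  uint16 = "uint16", `unsigned short` = "uint16",
                  float = "float32",
                  stop("unsupported NRRD type: ", type))
  encoding <- tolower(fields$encoding)
  if (encoding %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "[ \t]+")[[1L]])
    vals <- vals[!is.na(vals)]
    if (length(vals) != n) stop("NRRD payload size mismatch: ", path)
    data <- vals
  } else if (encoding == "raw") {
    if (!is.null(fields$endian) && tolower(fields$endian) == "big") {
      stop("big-endian NRRD not supported")
    }
    if (dtype == "uint8") {
      data <- as.integer(readBin(con, "raw", n = n))
    } else if (dtype == "uint16") {
      b <- as.integer(readBin(con, "raw", n = 2L * n))
      data <- b[seq(1L, 2L * n, 2L)] + 256L * b[seq(2L, 2L * n, 2L)]
    } else {
      data <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    }
    if (length(data) != n) stop("NRRD payload size mismatch: ", path)
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  spacings <- NULL
  if (!is.null(fields$spacings)) {
    spacings <- as.numeric(strsplit(fields$spacings, "[ \t]+")[[1L]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- fields[["space directions"]]
    rows <- regmatches(dirs, gregexpr("\\(([^)]*)\\)", dirs))[[1L]]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1L]])
    }, numeric(3)))
    offdiag <- m - diag(diag(m))
    if (max(abs(offdiag)) > 1e-9) stop("oblique NRRD axes not supported")
    spacings <- diag(m)
  }
  og <- NULL
  if (!is.null(fields[["axis mins"]])) {
    og <- as.numeric(strsplit(fields[["axis mins"]], "[ \t]+")[[1L]])
  } else if (!is.null(fields[["space origin"]])) {
    og <- as.numeric(strsplit(gsub("[()]", "",
                                   fields[["space origin"]]), ",")[[1L]])
  }
  list(data = data, sizes = sizes, dtype = dtype, spacings = spacings,
       origin = og)
}

## ---- landmarks ----------------------------------------------------------

#' Construct a LandmarkSet
#'
#' @param fixedPoints,movingPoints n x 3 matrices of paired world
#'   coordinates (um) in the fixed and moving volumes.
#' @param labels optional landmark names.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(fixedPoints, movingPoints, labels = character()) {
  new("LandmarkSet",
      fixedPoints = rbind(fixedPoints) * 1.0,
      movingPoints = rbind(movingPoints) * 1.0,
      labels = as.character(labels))
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d paired points\n", nrow(object@fixedPoints)))
})

#' Number of landmark pairs
#' @param x a [LandmarkSet-class].
#' @export
setMethod("length", "LandmarkSet", function(x) nrow(x@fixedPoints))

#' @rdname landmarkSet
#' @param x a [LandmarkSet-class].
#' @export
fixedPoints <- function(x) x@fixedPoints

#' @rdname landmarkSet
#' @export
movingPoints <- function(x) x@movingPoints

#' Read paired landmarks from CSV
#'
#' Expected columns: \code{label} (optional), \code{fixed_1..3} and
#' \code{moving_1..3} -- world um in (depth, row, column) axis order.
#'
#' @param path CSV path.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c(paste0("fixed_", 1:3), paste0("moving_", 1:3))
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  }
  landmarkSet(as.matrix(df[, paste0("fixed_", 1:3)]),
              as.matrix(df[, paste0("moving_", 1:3)]),
              labels = if ("label" %in% names(df)) {
                as.character(df$label)
              } else character())
}

#' Write paired landmarks to CSV
#'
#' @param lm a [LandmarkSet-class].
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarks <- function(lm, path) {
  df <- data.frame(
    label = if (length(lm@labels)) lm@labels else
      paste0("p", seq_len(nrow(lm@fixedPoints))),
    fixed_1 = lm@fixedPoints[, 1], fixed_2 = lm@fixedPoints[, 2],
    fixed_3 = lm@fixedPoints[, 3],
    moving_1 = lm@movingPoints[, 1], moving_2 = lm@movingPoints[, 2],
    moving_3 = lm@movingPoints[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- transform serialization -------------------------------------------

#' Write a transform to JSON (+ NRRD for field stages)
#'
#' Similarity stages are stored as row-major 4x4 matrices in um; each
#' displacement-field stage is stored as a 4D NRRD (components fastest)
#' next to the JSON file, referenced by relative name.
#'
#' @param t a [SimilarityTransform-class], [DisplacementField-class] or
#'   [CompositeTransform-class].
#' @param path destination .json path.
#' @return \code{path}, invisibly.
#' @export
writeTransform <- function(t, path) {
  t <- as(t, "CompositeTransform")
  stages <- list()
  nf <- 0L
  for (i in seq_along(t@stages)) {
    st <- t@stages[[i]]
    if (is(st, "SimilarityTransform")) {
      stages[[i]] <- list(type = "similarity",
                          matrix_row_major = as.vector(t(st@matrix)))
    } else {
      nf <- nf + 1L
      fname <- sprintf("%s_field%d.nrrd",
                       tools::file_path_sans_ext(basename(path)), nf)
      vec <- aperm(st@vectors, c(4, 1, 2, 3))  # components fastest
      .writeNRRD(vec, file.path(dirname(path), fname), dtype = "float32",
                 spacing = st@nodeSpacing, origin = c(0, st@origin))
      stages[[i]] <- list(type = "displacement_field", file = fname,
                          node_spacing_um = st@nodeSpacing,
                          origin_um = st@origin,
                          sizes = dim(st@vectors)[1:3])
    }
  }
  jsonlite::write_json(list(format = "voxalign-transform",
                            units = "um",
                            convention = "moving_to_fixed_world",
                            stages = stages),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform written by [writeTransform()]
#'
#' @param path .json path.
#' @return a [CompositeTransform-class].
#' @export
readTransform <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  stages <- list()
  n <- if (is.data.frame(js$stages)) nrow(js$stages) else length(js$stages)
  getStage <- function(i) {
    if (is.data.frame(js$stages)) lapply(js$stages, `[[`, i) else
      js$stages[[i]]
  }
  for (i in seq_len(n)) {
    st <- getStage(i)
    if (st$type == "similarity") {
      m <- matrix(unlist(st$matrix_row_major), 4, 4, byrow = TRUE)
      stages[[i]] <- similarityTransform(m)
    } else {
      nr <- .readNRRD(file.path(dirname(path), st$file))
      vec <- aperm(array(nr$data, nr$sizes), c(2, 3, 4, 1))
      stages[[i]] <- displacementField(vec,
                                       nodeSpacing = st$node_spacing_um,
                                       origin = unlist(st$origin_um))
    }
  }
  compositeTransform(stages)
}
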