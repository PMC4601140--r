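#' Read a 2-D magnitude image
#'
#' Reads NIfTI (`.nii`, `.nii.gz`), PNG or TIFF into a
#' [MagnitudeImage-class]. NIfTI spacing comes from the header pixdim;
#' 3-D NIfTI volumes require a `slice` selector (processing is per slice).
#' PNG and TIFF intensities are rescaled through the sidecar JSON written
#' by [writeImage()] when one is present, otherwise returned as stored
#' (0--1) with a warning. Negative values are rejected: the pipeline
#' operates on magnitude data. Formats without spacing metadata fall back
#' to 1 mm with a warning.
#'
#' @param path input file.
#' @param slice 1-based slice index for 3-D NIfTI volumes.
#' @return A [MagnitudeImage-class].
#' @export
readImage <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*?(\\.nii(\\.gz)?|\\.[a-z0-9]+)$", "\\1",
                     basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    arr <- as.array(img)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] == 1L) slice <- 1L
      if (is.null(slice))
        stop("3-D NIfTI input: supply a 'slice' selector")
      arr <- arr[, , slice]
    } else if (length(dim(arr)) != 2L) {
      stop("unsupported NIfTI dimensionality: ", length(dim(arr)))
    }
    if (any(arr < 0)) stop("negative values: not a magnitude image")
    return(magnitudeImage(arr, spacing = pd[1:2],
                          meta = list(source = path)))
  }
  if (ext == ".png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]    # greyscale from RGB
    sidecar <- paste0(path, ".json")
    spacing <- c(1, 1)
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      arr <- arr * (sc$max - sc$min) + sc$min
      if (!is.null(sc$spacing_mm)) spacing <- sc$spacing_mm
    } else {
      warning("no sidecar for ", basename(path),
              ": intensities left on the stored 0-1 scale, spacing 1 mm")
    }
    return(magnitudeImage(arr, spacing = spacing,
                          meta = list(source = path)))
  }
  if (ext %in% c(".tif", ".tiff")) {
    arr <- tiff::readTIFF(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    sidecar <- paste0(path, ".json")
    spacing <- c(1, 1)
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      arr <- arr * (sc$max - sc$min) + sc$min
      if (!is.null(sc$spacing_mm)) spacing <- sc$spacing_mm
    } else {
      warning("no sidecar for ", basename(path),
              ": intensities left on the stored 0-1 scale, spacing 1 mm")
    }
    if (any(arr < 0)) stop("negative values: not a magnitude image")
    return(magnitudeImage(arr, spacing = spacing,
                          meta = list(source = path)))
  }
  stop("unknown image format: ", ext)
}

#' Write a 2-D magnitude image
#'
#' Format follows the extension. NIfTI output preserves the spacing in the
#' header (32-bit float data). PNG output is rescaled to 16 bits, TIFF to
#' 32-bit float on the unit interval; both record the scaling (and
#' spacing) in a `<file>.json` sidecar so that [readImage()] restores the
#' original values.
#'
#' @param record a [MagnitudeImage-class].
#' @param path output file (`.nii`, `.nii.gz`, `.png`, `.tif`).
#' @return Invisibly, `path`.
#' @export
writeImage <- function(record, path) {
  stopifnot(is(record, "MagnitudeImage"))
  ext <- tolower(sub(".*?(\\.nii(\\.gz)?|\\.[a-z0-9]+)$", "\\1",
                     basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(record@data)
    RNifti::pixdim(img) <- record@spacing
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (ext == ".png") {
    lo <- min(record@data); hi <- max(record@data)
    scl <- if (hi > lo) (record@data - lo) / (hi - lo)
           else matrix(0, nrow(record@data), ncol(record@data))
    png::writePNG(scl, path, dpi = NULL)
    jsonlite::write_json(list(min = lo, max = hi,
                              spacing_mm = record@spacing),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext %in% c(".tif", ".tiff")) {
    lo <- min(record@data); hi <- max(record@data)
    scl <- if (hi > lo) (record@data - lo) / (hi - lo)
           else matrix(0, nrow(record@data), ncol(record@data))
    tiff::writeTIFF(scl, path, bits.per.sample = 32L)
    jsonlite::write_json(list(min = lo, max = hi,
                              spacing_mm = record@spacing),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    stop("unknown image format: ", ext)
  }
  invisible(path)
}

.coilSchema <- c("type", "surface", "surface_gain", "tau_mm", "d_cut_mm",
                 "floor_gain")
.samplerSchema <- c("patch_radius", "search_radius", "n_accept",
                    "max_draws", "seed")
.scaleFieldSchema <- c("window_radius")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML key-value configuration with sections `coil`, `sampler`
#' and `scale_field`. Every key is validated against the documented
#' schema; unknown keys are rejected (fail fast) with all offending keys
#' enumerated. Missing keys take the documented defaults, so an empty
#' file yields the full default configuration. Surface coordinates in the
#' file use the 0-based row-major interchange convention and are
#' converted to 1-based R indices on load.
#'
#' Schema (defaults in parentheses):
#' \itemize{
#'   \item coil: `type` ("rigid" | "inflatable"; "rigid"), `surface`
#'     ("bottom-edge" or a list of one or two 0-based (row, col) pairs;
#'     "bottom-edge"), `surface_gain` (5 rigid / 2 inflatable), `tau_mm`
#'     (20), `d_cut_mm` (60), `floor_gain` (1).
#'   \item sampler: `patch_radius` (3), `search_radius` (10), `n_accept`
#'     (32), `max_draws` (128), `seed` (1).
#'   \item scale_field: `window_radius` (8).
#' }
#'
#' @param path YAML file; missing sections and an empty file are allowed.
#' @return Validated configuration list with elements `coil` (a list),
#'   `sampler` (a [SamplerConfig-class]) and `scaleField` (a list).
#' @export
loadConfig <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("file not found: ", path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("coil", "sampler", "scale_field"))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  co <- raw$coil %||% list()
  sa <- raw$sampler %||% list()
  sf <- raw$scale_field %||% list()
  bad <- c(
    if (length(b <- setdiff(names(co), .coilSchema)))
      paste0("coil.", b),
    if (length(b <- setdiff(names(sa), .samplerSchema)))
      paste0("sampler.", b),
    if (length(b <- setdiff(names(sf), .scaleFieldSchema)))
      paste0("scale_field.", b))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))

  type <- co$type %||% "rigid"
  if (!type %in% c("rigid", "inflatable"))
    stop("coil.type must be \"rigid\" or \"inflatable\"")
  gain <- co$surface_gain %||% (if (type == "rigid") 5 else 2)
  if (gain < 1) stop("coil.surface_gain must be >= 1")
  tau <- co$tau_mm %||% 20
  if (tau <= 0) stop("coil.tau_mm must be > 0")
  dcut <- co$d_cut_mm %||% 60
  if (dcut <= 0) stop("coil.d_cut_mm must be > 0")
  floorg <- co$floor_gain %||% 1
  if (floorg < 0 || floorg > gain)
    stop("coil.floor_gain must be in [0, surface_gain]")
  surface <- co$surface %||% "bottom-edge"
  if (!identical(surface, "bottom-edge")) {
    surface <- do.call(rbind, lapply(surface, as.numeric))
    if (ncol(surface) != 2L || !nrow(surface) %in% c(1L, 2L))
      stop("coil.surface must be one or two (row, col) pairs")
    surface <- surface + 1      # 0-based file convention -> 1-based R
  }

  cfg <- samplerConfig(
    patchRadius = sa$patch_radius %||% 3,
    searchRadius = sa$search_radius %||% 10,
    nAccept = sa$n_accept %||% 32,
    maxDraws = sa$max_draws %||% (4 * (sa$n_accept %||% 32)),
    seed = sa$seed %||% 1)
  list(coil = list(type = type, surface = surface, surfaceGain = gain,
                   decayLength = tau, cutoffDistance = dcut,
                   floorGain = floorg),
       sampler = cfg,
       scaleField = list(windowRadius = sf$window_radius %||% 8))
}

#' Resolve a configuration coil section against an image
#'
#' Turns the `coil` element of [loadConfig()] output into a
#' [CoilModel-class] for a given image shape ("bottom-edge" becomes a
#' segment along the last row).
#'
#' @param coilConf the `coil` element of a loaded configuration.
#' @param shape image dimensions (rows, cols).
#' @return A [CoilModel-class].
#' @export
buildCoil <- function(coilConf, shape) {
  surface <- coilConf$surface
  if (identical(surface, "bottom-edge"))
    surface <- rbind(c(shape[1], 1), c(shape[1], shape[2]))
  coilModel(coilConf$type, surface = surface,
            surfaceGain = coilConf$surfaceGain,
            decayLength = coilConf$decayLength,
            cutoffDistance = coilConf$cutoffDistance,
            floorGain = coilConf$floorGain)
}

#' Write a coil configuration file
#'
#' @param coil a [CoilModel-class].
#' @param path YAML output path. Surface coordinates are written 0-based
#'   per the interchange convention.
#' @return Invisibly, `path`.
#' @export
writeCoilConfig <- function(coil, path) {
  stopifnot(is(coil, "CoilModel"))
  yaml::write_yaml(list(coil = list(
    type = coil@coilType,
    surface = lapply(seq_len(nrow(coil@surface)),
                     function(i) as.numeric(coil@surface[i, ] - 1)),
    surface_gain = coil@surfaceGain,
    tau_mm = coil@decayLength,
    d_cut_mm = coil@cutoffDistance,
    floor_gain = coil@floorGain)), path)
  invisible(path)
}

#' Write region specifications to JSON
#'
#' @param regions named list of [regionRect()] objects.
#' @param path JSON output path. Rectangles are written as 0-based
#'   inclusive (row, col) ranges.
#' @return Invisibly, `path`.
#' @export
writeRegions <- function(regions, path) {
  out <- lapply(regions, function(r)
    list(label = r$label, rows = as.integer(r$rows - 1L),
         cols = as.integer(r$cols - 1L)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read region specifications from JSON
#'
#' @param path JSON file written by [writeRegions()] (0-based inclusive
#'   ranges).
#' @return Named list of [regionRect()] objects (1-based).
#' @export
readRegions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(r)
    regionRect(r$label, rows = r$rows + 1L, cols = r$cols + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
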