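#' Create a MagnitudeImage
#'
#' @param data numeric matrix of non-negative intensities.
#' @param spacing mm per pixel along (row, column); a single value is
#'   recycled to both axes.
#' @param meta optional list of pass-through metadata.
#' @return A [MagnitudeImage-class] object.
#' @examples
#' img <- magnitudeImage(matrix(runif(64), 8, 8), spacing = 0.5)
#' dim(imageData(img))
#' @export
magnitudeImage <- function(data, spacing = c(1, 1), meta = list()) {
  if (is.null(dim(data))) data <- as.matrix(data)
  # strip any foreign class/attributes (e.g. niftiImage) down to a matrix
  data <- matrix(as.double(data), nrow(data), ncol(data))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  new("MagnitudeImage", data = data, spacing = as.numeric(spacing),
      meta = meta)
}

#' Create a CoilModel
#'
#' Defaults follow published endorectal-coil SNR depth profiles: a rigid
#' coil gains about 5x SNR at its surface, an inflatable coil about 2x,
#' with an exponential decay and a final abrupt drop. The inflatable
#' default of 2 is a modelling choice: a "1-fold improvement" at the
#' surface is ambiguous between no gain and a doubling, and a doubling
#' keeps the profile informative.
#'
#' @param coilType "rigid" or "inflatable".
#' @param surface coil-surface geometry in 1-based pixel coordinates: a
#'   numeric vector (row, col) for a point coil, or a 2 x 2 matrix whose
#'   rows are the endpoints of a line segment.
#' @param surfaceGain SNR multiple A at the coil surface; defaults to 5
#'   (rigid) or 2 (inflatable).
#' @param decayLength exponential decay length tau, mm.
#' @param cutoffDistance distance of the final abrupt drop, mm.
#' @param floorGain gain beyond the cutoff.
#' @return A [CoilModel-class] object.
#' @examples
#' coil <- coilModel("rigid", surface = c(96, 48))
#' snrGain(0, coil)
#' @export
coilModel <- function(coilType = c("rigid", "inflatable"), surface,
                      surfaceGain = NULL, decayLength = 20,
                      cutoffDistance = 60, floorGain = 1) {
  coilType <- match.arg(coilType)
  if (is.null(surfaceGain))
    surfaceGain <- if (coilType == "rigid") 5 else 2
  if (is.null(dim(surface))) surface <- matrix(surface, nrow = 1L)
  new("CoilModel", coilType = coilType,
      surface = matrix(as.numeric(surface), nrow = nrow(surface)),
      surfaceGain = as.numeric(surfaceGain),
      decayLength = as.numeric(decayLength),
      cutoffDistance = as.numeric(cutoffDistance),
      floorGain = as.numeric(floorGain))
}

#' Create a SamplerConfig
#'
#' @param patchRadius neighbourhood radius in pixels (default 3, a 7x7
#'   patch).
#' @param searchRadius search-window radius in pixels (default 10, a 21x21
#'   window).
#' @param nAccept target number of accepted samples N (default 32; the
#'   centre pixel counts).
#' @param maxDraws cap on candidate draws (default 4 * nAccept).
#' @param seed integer seed for the sampler's random stream.
#' @param forceAccept accept every candidate (validation mode).
#' @return A [SamplerConfig-class] object.
#' @examples
#' cfg <- samplerConfig(seed = 7)
#' cfg
#' @export
samplerConfig <- function(patchRadius = 3, searchRadius = 10, nAccept = 32,
                          maxDraws = 4 * nAccept, seed = 1,
                          forceAccept = FALSE) {
  new("SamplerConfig", patchRadius = as.integer(patchRadius),
      searchRadius = as.integer(searchRadius),
      nAccept = as.integer(nAccept), maxDraws = as.integer(maxDraws),
      seed = as.integer(seed), forceAccept = isTRUE(forceAccept))
}

#' Create a ScoreTable from a data frame or CSV file
#'
#' @param scores data.frame with columns evaluator, slice, criterion,
#'   score (integers 1--5), or the path of a CSV file with those columns.
#' @return A [ScoreTable-class] object.
#' @examples
#' df <- expand.grid(evaluator = 1:3, slice = 1:2, criterion = "contrast")
#' df$score <- 4L
#' rankSum(scoreTable(df), "contrast")
#' @export
scoreTable <- function(scores) {
  if (is.character(scores) && length(scores) == 1L)
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  scores <- as.data.frame(scores)
  scores$criterion <- as.character(scores$criterion)
  new("ScoreTable", scores = scores)
}
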