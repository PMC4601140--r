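#' @rdname MagnitudeImage-class
#' @export
setMethod("imageData", "MagnitudeImage", function(x) x@data)

#' @rdname MagnitudeImage-class
#' @export
setMethod("pixelSpacing", "MagnitudeImage", function(x) x@spacing)

#' @rdname MagnitudeImage-class
#' @export
setMethod("dim", "MagnitudeImage", function(x) dim(x@data))

setMethod("show", "MagnitudeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("MagnitudeImage: %d x %d pixels, spacing %.3g x %.3g mm\n",
              d[1], d[2], object@spacing[1], object@spacing[2]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' @rdname CoilModel-class
#' @export
setMethod("coilType", "CoilModel", function(x) x@coilType)

setMethod("show", "CoilModel", function(object) {
  geom <- if (nrow(object@surface) == 1L) "point" else "segment"
  cat(sprintf("CoilModel (%s ERC, %s surface)\n", object@coilType, geom))
  cat(sprintf("  surface gain A = %.3g, decay tau = %.3g mm, cutoff = %.3g mm, floor = %.3g\n",
              object@surfaceGain, object@decayLength, object@cutoffDistance,
              object@floorGain))
})

#' @rdname NoiseScaleField-class
#' @export
setMethod("scaleField", "NoiseScaleField", function(x) x@phi)

#' @rdname NoiseScaleField-class
#' @export
setMethod("baseScale", "NoiseScaleField", function(x) x@baseScale)

#' @rdname NoiseScaleField-class
#' @export
setMethod("distanceField", "NoiseScaleField", function(x) x@distance)

setMethod("show", "NoiseScaleField", function(object) {
  cat(sprintf("NoiseScaleField: %d x %d, base scale Phi0 = %.4g\n",
              nrow(object@phi), ncol(object@phi), object@baseScale))
  cat(sprintf("  Phi range [%.4g, %.4g]\n", min(object@phi), max(object@phi)))
})

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf(
    "SamplerConfig: patch %dpx (%dx%d), search %dpx (%dx%d), N = %d, maxDraws = %d, seed = %d%s\n",
    object@patchRadius, 2L * object@patchRadius + 1L, 2L * object@patchRadius + 1L,
    object@searchRadius, 2L * object@searchRadius + 1L, 2L * object@searchRadius + 1L,
    object@nAccept, object@maxDraws, object@seed,
    if (object@forceAccept) " (force-accept)" else ""))
})

#' @rdname SampleSet-class
#' @export
setMethod("sampleWeights", "SampleSet", function(x) x@weights)

#' @rdname SampleSet-class
#' @export
setMethod("sampleValues", "SampleSet", function(x) x@values)

#' @rdname SampleSet-class
#' @export
setMethod("sampleLocations", "SampleSet", function(x) x@locations)

#' @rdname SampleSet-class
#' @export
setMethod("length", "SampleSet", function(x) nrow(x@locations))

setMethod("show", "SampleSet", function(object) {
  cat(sprintf("SampleSet at (%d, %d): %d accepted samples, weight range [%.3g, %.3g]\n",
              object@center[1], object@center[2], nrow(object@locations),
              min(object@weights), max(object@weights)))
})

setMethod("show", "PosteriorEstimate", function(object) {
  cat(sprintf("PosteriorEstimate: %d support points, Z = %.4g, mean = %.4g\n",
              length(object@support), object@Z,
              sum(object@support * object@mass)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px at %.3g x %.3g mm, %d lesion(s), sigma0 = %.3g, seed = %d\n",
              object@shape[1], object@shape[2], object@spacing[1],
              object@spacing[2], nrow(object@lesionCenters), object@sigma0,
              object@seed))
})

#' @rdname ScoreTable-class
#' @export
setMethod("scoreValues", "ScoreTable", function(x, criterion) {
  df <- x@scores[x@scores$criterion == criterion, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no scores for criterion '", criterion, "'")
  as.numeric(df$score)
})

setMethod("show", "ScoreTable", function(object) {
  df <- object@scores
  cat(sprintf("ScoreTable: %d evaluators x %d slices, criteria: %s\n",
              length(unique(df$evaluator)), length(unique(df$slice)),
              paste(unique(df$criterion), collapse = ", ")))
})
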