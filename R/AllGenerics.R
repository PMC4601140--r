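#' @rdname MagnitudeImage-class
#' @param object,x an object.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname MagnitudeImage-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname NoiseScaleField-class
#' @export
setGeneric("scaleField", function(x) standardGeneric("scaleField"))

#' @rdname NoiseScaleField-class
#' @export
setGeneric("baseScale", function(x) standardGeneric("baseScale"))

#' @rdname NoiseScaleField-class
#' @export
setGeneric("distanceField", function(x) standardGeneric("distanceField"))

#' @rdname CoilModel-class
#' @export
setGeneric("coilType", function(x) standardGeneric("coilType"))

#' @rdname SampleSet-class
#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))

#' @rdname SampleSet-class
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))

#' @rdname SampleSet-class
#' @export
setGeneric("sampleLocations", function(x) standardGeneric("sampleLocations"))

#' @rdname ScoreTable-class
#' @param criterion name of a scoring criterion present in the table.
#' @export
setGeneric("scoreValues", function(x, criterion) standardGeneric("scoreValues"))
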