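#' @import methods
NULL

#' MagnitudeImage: a 2-D MR magnitude image with physical spacing
#'
#' Container for a single 2-D magnitude image (one slice), the object every
#' stage of the pipeline consumes and produces. Intensities must be finite
#' and non-negative (magnitude data); pixel spacing is in millimetres per
#' pixel along (row, column).
#'
#' @slot data numeric matrix of intensities, finite and >= 0.
#' @slot spacing numeric(2), mm per pixel along (row, column).
#' @slot meta list of pass-through metadata (e.g. NIfTI header fields).
#'
#' @seealso [magnitudeImage()], [readImage()], [acerReconstruct()]
#' @export
setClass("MagnitudeImage",
  representation(data = "matrix", spacing = "numeric", meta = "list"),
  prototype(spacing = c(1, 1), meta = list()))

setValidity("MagnitudeImage", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (length(d) == 0L) return("'data' must be non-empty")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("magnitude intensities must be >= 0")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be two positive values (mm per pixel)")
  TRUE
})

#' CoilModel: parametric endorectal-coil SNR depth profile
#'
#' Describes the SNR-gain profile of an endorectal receiver coil (ERC) as a
#' function of distance from the coil surface. Rigid coils show roughly a
#' 3--5x SNR gain at the surface, inflatable coils a weaker response; both
#' decay with distance. The profile implemented is an exponential decay to a
#' floor with an abrupt drop at a cutoff distance:
#' \deqn{\gamma(d) = g_f + (A - g_f) e^{-d/\tau},\ d \le d_{cut};\qquad
#'       \gamma(d) = g_f,\ d > d_{cut}.}
#'
#' @slot coilType character, "rigid" or "inflatable".
#' @slot surface numeric matrix with 1 row (point coil) or 2 rows (line
#'   segment), columns (row, col) in 1-based pixel coordinates.
#' @slot surfaceGain unitless SNR multiple A at the coil surface (>= 1).
#' @slot decayLength exponential decay length tau in mm (> 0).
#' @slot cutoffDistance distance of the final abrupt drop, mm (> 0).
#' @slot floorGain unitless gain beyond the cutoff (>= 0, <= A).
#'
#' @seealso [coilModel()], [snrGain()], [distanceMap()]
#' @export
setClass("CoilModel",
  representation(coilType = "character", surface = "matrix",
                 surfaceGain = "numeric", decayLength = "numeric",
                 cutoffDistance = "numeric", floorGain = "numeric"))

setValidity("CoilModel", function(object) {
  if (length(object@coilType) != 1L ||
      !object@coilType %in% c("rigid", "inflatable"))
    return("'coilType' must be \"rigid\" or \"inflatable\"")
  s <- object@surface
  if (!is.numeric(s) || ncol(s) != 2L || !nrow(s) %in% c(1L, 2L) ||
      any(!is.finite(s)))
    return("'surface' must be a 1- or 2-row numeric matrix of (row, col)")
  if (length(object@surfaceGain) != 1L || object@surfaceGain < 1)
    return("'surfaceGain' (A) must be a single value >= 1")
  if (length(object@decayLength) != 1L || object@decayLength <= 0)
    return("'decayLength' (tau, mm) must be > 0")
  if (length(object@cutoffDistance) != 1L || object@cutoffDistance <= 0)
    return("'cutoffDistance' (mm) must be > 0")
  if (length(object@floorGain) != 1L || object@floorGain < 0)
    return("'floorGain' must be >= 0")
  if (object@floorGain > object@surfaceGain)
    return("'floorGain' must not exceed 'surfaceGain' (profile must be non-increasing)")
  TRUE
})

#' NoiseScaleField: per-pixel Rician scale of a corrected image
#'
#' The non-stationary noise model for a pre-calibration corrected image:
#' the Rician scale at pixel s is \eqn{\Phi(s) = \Phi_0 / \gamma(d(s))},
#' where \eqn{\gamma} is the coil SNR profile and d(s) the distance to the
#' coil surface. Produced by [fitScaleField()].
#'
#' @slot phi numeric matrix, per-pixel Rician scale (intensity units, > 0).
#' @slot baseScale base scale Phi0 (the raw-acquisition noise level).
#' @slot distance numeric matrix, per-pixel distance to the coil surface (mm).
#'
#' @seealso [fitScaleField()], [acerReconstruct()]
#' @export
setClass("NoiseScaleField",
  representation(phi = "matrix", baseScale = "numeric", distance = "matrix"))

setValidity("NoiseScaleField", function(object) {
  if (any(!is.finite(object@phi)) || any(object@phi <= 0))
    return("'phi' must be finite and > 0 everywhere")
  if (length(object@baseScale) != 1L || object@baseScale <= 0)
    return("'baseScale' must be a single positive value")
  if (!identical(dim(object@phi), dim(object@distance)))
    return("'phi' and 'distance' must have identical dimensions")
  TRUE
})

#' SamplerConfig: settings for the Monte Carlo posterior sampler
#'
#' @slot patchRadius neighbourhood radius h in pixels (patch is
#'   (2h+1) x (2h+1)).
#' @slot searchRadius search-window radius in pixels (window eta is
#'   (2r+1) x (2r+1), clipped to the image).
#' @slot nAccept target number N of accepted samples (the centre pixel
#'   counts towards N).
#' @slot maxDraws cap on candidate draws per pixel.
#' @slot seed integer seed driving both the instrumental distribution and
#'   the uniform acceptance variates; a per-pixel substream is derived from
#'   it so results do not depend on pixel processing order.
#' @slot forceAccept logical; if TRUE every drawn candidate is accepted
#'   (acceptance variate treated as 0), used for exhaustive-window
#'   validation against a direct weighted-mean computation.
#'
#' @seealso [samplerConfig()], [drawSamples()], [acerReconstruct()]
#' @export
setClass("SamplerConfig",
  representation(patchRadius = "integer", searchRadius = "integer",
                 nAccept = "integer", maxDraws = "integer",
                 seed = "integer", forceAccept = "logical"))

setValidity("SamplerConfig", function(object) {
  if (object@patchRadius < 1L) return("'patchRadius' must be >= 1")
  if (object@searchRadius <= object@patchRadius)
    return("'searchRadius' must exceed 'patchRadius'")
  nWin <- (2L * object@searchRadius + 1L)^2
  if (object@nAccept < 1L || object@nAccept > nWin)
    return("'nAccept' must be in [1, window size]")
  if (object@maxDraws < object@nAccept)
    return("'maxDraws' must be >= 'nAccept'")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("'seed' must be a single integer")
  TRUE
})

#' SampleSet: accepted Monte Carlo samples at one pixel
#'
#' The set Omega of accepted sample locations with their importance weights
#' alpha and observed values, for a single pixel of interest. The centre
#' pixel is always a member with weight 1, so the set is never empty.
#'
#' @slot center integer(2), (row, col) of the pixel of interest (1-based).
#' @slot locations n x 2 integer matrix of accepted (row, col) locations.
#' @slot weights numeric acceptance probabilities alpha in (0, 1].
#' @slot values observed intensities V at the accepted locations.
#'
#' @seealso [drawSamples()], [posteriorEstimate()]
#' @export
setClass("SampleSet",
  representation(center = "integer", locations = "matrix",
                 weights = "numeric", values = "numeric"))

setValidity("SampleSet", function(object) {
  n <- nrow(object@locations)
  if (n == 0L) return("a SampleSet is never empty (centre always included)")
  if (length(object@weights) != n || length(object@values) != n)
    return("'locations', 'weights' and 'values' must agree in length")
  if (any(object@weights <= 0) || any(object@weights > 1))
    return("weights must lie in (0, 1]")
  TRUE
})

#' PosteriorEstimate: weighted point-mass posterior at one pixel
#'
#' Nonparametric posterior of the noise-free intensity at a pixel: point
#' masses at the accepted sample values, with mass proportional to the
#' acceptance weights, normalised by Z to sum to one.
#'
#' @slot support distinct intensity values carrying mass.
#' @slot mass probabilities (>= 0, summing to 1 within 1e-12).
#' @slot Z the normaliser (sum of acceptance weights).
#'
#' @seealso [posteriorEstimate()], [blsEstimate()]
#' @export
setClass("PosteriorEstimate",
  representation(support = "numeric", mass = "numeric", Z = "numeric"))

setValidity("PosteriorEstimate", function(object) {
  if (length(object@support) != length(object@mass))
    return("'support' and 'mass' must agree in length")
  if (any(object@mass < 0)) return("masses must be >= 0")
  if (abs(sum(object@mass) - 1) > 1e-12)
    return("masses must sum to 1 within 1e-12")
  if (object@Z <= 0) return("'Z' must be positive")
  TRUE
})

#' PhantomSpec: geometry of the synthetic prostate phantom
#'
#' Piecewise-homogeneous digital phantom modelled on commercial prostate
#' training phantoms: a prostate ellipse in a uniform background, three
#' hypointense lesions inside the gland, and a urethra disc. All geometry
#' is in millimetres; [makePhantom()] rasterises it on the pixel grid.
#'
#' @slot shape integer(2), image dimensions in pixels (rows, cols).
#' @slot spacing numeric(2), mm per pixel.
#' @slot prostateCenter numeric(2), ellipse centre (row, col) in mm.
#' @slot prostateAxes numeric(2), ellipse semi-axes (row, col) in mm.
#' @slot prostateIntensity intensity of the gland.
#' @slot lesionCenters k x 2 matrix of lesion centres in mm (may have 0 rows).
#' @slot lesionRadii lesion radii in mm.
#' @slot lesionIntensity intensity of the lesions (hypointense to the gland).
#' @slot urethraCenter numeric(2), urethra disc centre in mm.
#' @slot urethraDiameter urethra diameter in mm.
#' @slot urethraIntensity intensity of the urethra.
#' @slot backgroundIntensity intensity outside the gland (0 = pure noise).
#' @slot sigma0 raw complex-channel noise sd (intensity units).
#' @slot seed integer seed for the acquisition simulation.
#'
#' @seealso [phantomSpec()], [makePhantom()], [simulateAcquisition()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 prostateCenter = "numeric", prostateAxes = "numeric",
                 prostateIntensity = "numeric",
                 lesionCenters = "matrix", lesionRadii = "numeric",
                 lesionIntensity = "numeric",
                 urethraCenter = "numeric", urethraDiameter = "numeric",
                 urethraIntensity = "numeric",
                 backgroundIntensity = "numeric",
                 sigma0 = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 8L))
    return("'shape' must be two pixel counts >= 8")
  if (any(object@spacing <= 0)) return("'spacing' must be positive (mm)")
  fov <- object@shape * object@spacing
  ints <- c(object@prostateIntensity, object@lesionIntensity,
            object@urethraIntensity, object@backgroundIntensity)
  if (any(ints < 0)) return("intensities must be >= 0")
  if (object@sigma0 <= 0) return("'sigma0' must be > 0")
  if (any(object@prostateAxes <= 0)) return("prostate semi-axes must be > 0")
  lo <- object@prostateCenter - object@prostateAxes
  hi <- object@prostateCenter + object@prostateAxes
  if (any(lo < 0) || any(hi > fov))
    return("prostate ellipse extends outside the field of view")
  k <- nrow(object@lesionCenters)
  if (k > 0L) {
    if (length(object@lesionRadii) != k)
      return("'lesionRadii' must match the number of lesion centres")
    if (any(object@lesionRadii <= 0)) return("lesion radii must be > 0")
    # lesion fully inside the prostate ellipse: shrink the ellipse by the
    # lesion radius along each axis and test the centre against it
    for (i in seq_len(k)) {
      ax <- object@prostateAxes - object@lesionRadii[i]
      if (any(ax <= 0)) return("lesion larger than the prostate")
      rel <- (object@lesionCenters[i, ] - object@prostateCenter) / ax
      if (sum(rel^2) > 1) return("lesions must lie inside the prostate ellipse")
    }
  }
  if (object@urethraDiameter <= 0) return("'urethraDiameter' must be > 0")
  rel <- (object@urethraCenter - object@prostateCenter) / object@prostateAxes
  if (sum(rel^2) > 1) return("urethra must lie inside the prostate ellipse")
  TRUE
})

#' ScoreTable: ordinal reader scores for subjective image assessment
#'
#' Scores on the 1--5 ordinal scale (very poor .. very good) given by N
#' evaluators to M slices for each assessment criterion (contrast,
#' sharpness, lack of noise, fitness for purpose). Feeds the rank-sum,
#' median and F-pseudosigma summaries.
#'
#' @slot scores data.frame with columns evaluator, slice, criterion, score.
#'
#' @seealso [scoreTable()], [rankSum()], [fPseudosigma()]
#' @export
setClass("ScoreTable", representation(scores = "data.frame"))

setValidity("ScoreTable", function(object) {
  df <- object@scores
  need <- c("evaluator", "slice", "criterion", "score")
  if (!all(need %in% names(df)))
    return(paste("score table needs columns:", paste(need, collapse = ", ")))
  s <- df$score
  if (length(s) == 0L) return("score table is empty")
  if (any(is.na(s)) || any(s != round(s)) || any(s < 1) || any(s > 5))
    return("scores must be integers in [1, 5]")
  if (anyDuplicated(df[c("evaluator", "slice", "criterion")]))
    return("duplicate (evaluator, slice, criterion) cells")
  TRUE
})
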