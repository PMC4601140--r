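#' Create a PhantomSpec
#'
#' Builds the geometry of the synthetic prostate phantom. Defaults mimic a
#' commercial prostate training phantom: a 5.0 x 4.5 cm gland ellipse
#' holding three hypointense lesions (radii 2.5--5 mm) and a 7 mm urethra,
#' placed in a signal-free background, rasterised at 0.3 mm spacing on a
#' 256 x 256 grid (76.8 mm field of view). Positions scale with the field
#' of view so smaller grids with coarser spacing keep the same anatomy.
#' The background intensity defaults to 0 so that background pixels are
#' pure noise, as assumed by the scale-field fit and matching the use of a
#' structure-free background region for SNR measurement.
#'
#' @param shape image dimensions in pixels.
#' @param spacing mm per pixel (scalar or length 2).
#' @param prostateIntensity,lesionIntensity,urethraIntensity,backgroundIntensity
#'   tissue intensities (arbitrary units, >= 0).
#' @param lesions number of lesions (0--3 of the default layout), or a
#'   list with elements `centers` (k x 2 matrix, mm), `radii` (mm).
#' @param sigma0 raw complex-channel noise standard deviation.
#' @param seed integer seed for the acquisition simulation.
#' @return A [PhantomSpec-class].
#' @examples
#' phantomSpec(shape = c(96, 96), spacing = 0.8)
#' @export
phantomSpec <- function(shape = c(256, 256), spacing = 0.3,
                        prostateIntensity = 200, lesionIntensity = 120,
                        urethraIntensity = 60, backgroundIntensity = 0,
                        lesions = 3, sigma0 = 10, seed = 1) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  fov <- shape * spacing
  ctr <- c(0.60, 0.50) * fov          # gland sits low, toward the coil
  axes <- c(22.5, 25)                 # semi-axes mm: 4.5 x 5.0 cm gland
  if (is.list(lesions)) {
    lc <- lesions$centers; lr <- lesions$radii
  } else {
    k <- as.integer(lesions)
    stopifnot(k >= 0L, k <= 3L)
    lc <- sweep(rbind(c(-8, -10), c(5, 8), c(10, -3))[seq_len(k), ,
                                                      drop = FALSE],
                2, ctr, "+")
    lr <- c(2.5, 3.5, 5)[seq_len(k)]
  }
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      prostateCenter = ctr, prostateAxes = axes,
      prostateIntensity = as.numeric(prostateIntensity),
      lesionCenters = matrix(as.numeric(lc), ncol = 2),
      lesionRadii = as.numeric(lr),
      lesionIntensity = as.numeric(lesionIntensity),
      urethraCenter = ctr + c(-10, 0), urethraDiameter = 7,
      urethraIntensity = as.numeric(urethraIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      sigma0 = as.numeric(sigma0), seed = as.integer(seed))
}

#' Rasterise the ground-truth phantom
#'
#' Deterministic piecewise-constant ground truth G: background, prostate
#' ellipse, urethra disc and hypointense lesions, each at its specified
#' intensity. Pixel centres are at (index - 1) * spacing mm.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [MagnitudeImage-class] ground truth.
#' @examples
#' G <- makePhantom(phantomSpec(shape = c(64, 64), spacing = 1.2))
#' sort(unique(as.vector(imageData(G))))
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@shape[1]; m <- spec@shape[2]
  pr <- matrix((seq_len(n) - 1) * spec@spacing[1], n, m)
  pc <- matrix((seq_len(m) - 1) * spec@spacing[2], n, m, byrow = TRUE)
  G <- matrix(spec@backgroundIntensity, n, m)
  inEll <- ((pr - spec@prostateCenter[1]) / spec@prostateAxes[1])^2 +
    ((pc - spec@prostateCenter[2]) / spec@prostateAxes[2])^2 <= 1
  G[inEll] <- spec@prostateIntensity
  inUr <- (pr - spec@urethraCenter[1])^2 + (pc - spec@urethraCenter[2])^2 <=
    (spec@urethraDiameter / 2)^2
  G[inUr] <- spec@urethraIntensity
  for (i in seq_len(nrow(spec@lesionCenters))) {
    inL <- (pr - spec@lesionCenters[i, 1])^2 +
      (pc - spec@lesionCenters[i, 2])^2 <= spec@lesionRadii[i]^2
    G[inL] <- spec@lesionIntensity
  }
  magnitudeImage(G, spacing = spec@spacing)
}

#' Simulate an uncorrected endorectal acquisition
#'
#' Applies the coil sensitivity field \eqn{B(s) = \gamma(d(s))} to the
#' ground truth and adds uniform complex Gaussian noise, returning the
#' magnitude: each pixel is \eqn{\sqrt{(B G + \sigma_0 Z_1)^2 +
#' (\sigma_0 Z_2)^2}}, i.e. Rician with location \eqn{B(s)G(s)} and
#' stationary scale \eqn{\sigma_0} -- the noise structure before any
#' intensity correction. Fully reproducible for a given seed.
#'
#' @param G ground truth ([MagnitudeImage-class] or matrix).
#' @param coil a [CoilModel-class].
#' @param sigma0 raw noise standard deviation (> 0).
#' @param seed integer seed.
#' @return A [MagnitudeImage-class], the uncorrected magnitude image.
#' @export
simulateAcquisition <- function(G, coil, sigma0, seed = 1) {
  G <- .asImage(G)
  stopifnot(is(coil, "CoilModel"))
  if (sigma0 <= 0) stop("'sigma0' must be > 0")
  B <- snrGain(distanceMap(dim(G@data), G@spacing, coil), coil)
  nu <- B * G@data
  U <- .withPreservedRNG({
    set.seed(as.integer(seed))
    sqrt((nu + sigma0 * stats::rnorm(length(nu)))^2 +
           (sigma0 * stats::rnorm(length(nu)))^2)
  })
  magnitudeImage(matrix(U, nrow(nu), ncol(nu)), spacing = G@spacing)
}

#' Apply pre-calibration coil intensity correction
#'
#' Division of the uncorrected image by the (known) sensitivity field, as
#' scanner-side pre-calibration correction does. The signal becomes
#' uniform but the stationary raw noise of scale \eqn{\sigma_0} becomes
#' non-stationary with scale \eqn{\sigma_0 / \gamma(d(s))}, growing with
#' distance from the coil -- the artefact the reconstruction compensates.
#'
#' @param uncorrected the simulated acquisition.
#' @param coil the same [CoilModel-class] used for simulation.
#' @return A [MagnitudeImage-class], the corrected image V.
#' @export
applyPrecalibrationCorrection <- function(uncorrected, coil) {
  U <- .asImage(uncorrected)
  stopifnot(is(coil, "CoilModel"))
  B <- snrGain(distanceMap(dim(U@data), U@spacing, coil), coil)
  if (any(B == 0))
    stop("configuration error: sensitivity is zero somewhere; use floorGain > 0")
  magnitudeImage(U@data / B, spacing = U@spacing)
}

#' Canonical measurement regions for a phantom
#'
#' A structure-free background region far from the coil (for SNR and the
#' noise term of CNR) and a homogeneous prostate region near the coil,
#' derived from the phantom geometry.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with elements `background` and `prostate`
#'   ([regionRect()] objects).
#' @export
phantomRegions <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@shape[1]; m <- spec@shape[2]
  sp <- spec@spacing
  px <- function(mm, axis) pmin(spec@shape[axis],
                                pmax(1L, as.integer(round(mm / sp[axis])) + 1L))
  # far background band: top of the image, well above the gland
  topEnd <- spec@prostateCenter[1] - spec@prostateAxes[1] - 5
  bg <- regionRect("background",
                   rows = c(px(1, 1), px(max(5, topEnd * 0.7), 1)),
                   cols = c(px(0.25 * m * sp[2], 2), px(0.75 * m * sp[2], 2)))
  # homogeneous gland rectangle on the coil side of the gland, inside
  # the ellipse and clear of the default lesions and the urethra
  pc <- spec@prostateCenter
  pro <- regionRect("prostate",
                    rows = c(px(pc[1] + 12, 1), px(pc[1] + 18, 1)),
                    cols = c(px(pc[2] + 5, 2), px(pc[2] + 9, 2)))
  list(background = bg, prostate = pro)
}

#' Write the canonical fixture suite
#'
#' Generates and writes the canonical small test set for a phantom: the
#' ground truth, the uncorrected acquisition and the corrected image
#' (NIfTI plus PNG previews), the coil configuration, the measurement
#' region specification (0-based indices in the JSON interchange
#' convention) and a manifest recording every generation parameter.
#' Regenerating with the same spec and seed is byte-identical.
#'
#' @param outDir writable output directory (created if needed).
#' @param seed integer seed (overrides the spec's seed).
#' @param spec a [PhantomSpec-class]; default is a 96 x 96 phantom at
#'   0.8 mm spacing (same field of view as the full-size default).
#' @param coil a [CoilModel-class]; default a rigid bottom-edge coil.
#' @return Invisibly, a list with the images, regions, coil and the paths
#'   written.
#' @export
makeFixtureSuite <- function(outDir, seed = 1,
                             spec = phantomSpec(shape = c(96, 96),
                                                spacing = 0.8, seed = seed),
                             coil = bottomEdgeCoil(spec@shape, "rigid")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  G <- makePhantom(spec)
  U <- simulateAcquisition(G, coil, spec@sigma0, seed = seed)
  V <- applyPrecalibrationCorrection(U, coil)
  regions <- phantomRegions(spec)

  paths <- list(
    ground_truth = file.path(outDir, "ground_truth.nii"),
    uncorrected = file.path(outDir, "uncorrected.nii"),
    corrected = file.path(outDir, "corrected.nii"),
    ground_truth_png = file.path(outDir, "ground_truth.png"),
    corrected_png = file.path(outDir, "corrected.png"),
    coil_config = file.path(outDir, "coil.yaml"),
    regions = file.path(outDir, "regions.json"),
    manifest = file.path(outDir, "manifest.json"))

  writeImage(G, paths$ground_truth)
  writeImage(U, paths$uncorrected)
  writeImage(V, paths$corrected)
  writeImage(G, paths$ground_truth_png)
  writeImage(V, paths$corrected_png)
  writeCoilConfig(coil, paths$coil_config)
  writeRegions(regions, paths$regions)

  manifest <- list(
    shape = spec@shape, spacing_mm = spec@spacing, seed = as.integer(seed),
    sigma0 = spec@sigma0,
    intensities = list(prostate = spec@prostateIntensity,
                       lesion = spec@lesionIntensity,
                       urethra = spec@urethraIntensity,
                       background = spec@backgroundIntensity),
    coil = list(type = coilType(coil), surface_gain = coil@surfaceGain,
                tau_mm = coil@decayLength, d_cut_mm = coil@cutoffDistance,
                floor_gain = coil@floorGain),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(groundTruth = G, uncorrected = U, corrected = V,
                 regions = regions, coil = coil, spec = spec, paths = paths))
}
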