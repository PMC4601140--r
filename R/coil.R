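#' Coil SNR gain at a given distance
#'
#' Evaluates the parametric endorectal-coil SNR profile
#' \eqn{\gamma(d) = g_f + (A - g_f)\,e^{-d/\tau}} for
#' \eqn{d \le d_{cut}} and \eqn{\gamma(d) = g_f} beyond the cutoff (the
#' final abrupt drop). \eqn{\gamma(0) = A}; the profile is non-increasing
#' for every valid [CoilModel-class].
#'
#' @param d distance(s) from the coil surface, mm, >= 0.
#' @param coil a [CoilModel-class].
#' @return Unitless gain values, same length as `d`.
#' @examples
#' coil <- coilModel("rigid", surface = c(1, 1))
#' snrGain(c(0, 20, 100), coil)
#' @export
snrGain <- function(d, coil) {
  stopifnot(is(coil, "CoilModel"))
  if (any(d < 0)) stop("domain error: distance must be >= 0")
  g <- coil@floorGain +
    (coil@surfaceGain - coil@floorGain) * exp(-d / coil@decayLength)
  g[d > coil@cutoffDistance] <- coil@floorGain
  g
}

# shortest distance (mm) from physical point p to the coil surface
# (point or segment with endpoints a, b, all in mm)
.distToSurface <- function(pr, pc, surf_mm) {
  if (nrow(surf_mm) == 1L) {
    return(sqrt((pr - surf_mm[1, 1])^2 + (pc - surf_mm[1, 2])^2))
  }
  a <- surf_mm[1, ]; b <- surf_mm[2, ]
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) return(sqrt((pr - a[1])^2 + (pc - a[2])^2))
  t <- ((pr - a[1]) * vr + (pc - a[2]) * vc) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

#' Distance-to-coil map
#'
#' Euclidean distance in millimetres from each pixel centre to the nearest
#' point of the coil surface (zero on the surface itself). Pixel centres
#' are at (index - 1) * spacing in physical coordinates.
#'
#' @param shape image dimensions (rows, cols) in pixels.
#' @param spacing mm per pixel along (row, column); a scalar is recycled.
#' @param coil a [CoilModel-class]; its surface must lie within the image.
#' @return Numeric matrix of distances, mm.
#' @examples
#' coil <- coilModel("rigid", surface = c(1, 1))
#' distanceMap(c(1, 3), spacing = 1, coil)   # 0, 1, 2 mm
#' @export
distanceMap <- function(shape, spacing, coil) {
  stopifnot(is(coil, "CoilModel"))
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  s <- coil@surface
  if (any(s[, 1] < 1) || any(s[, 1] > shape[1]) ||
      any(s[, 2] < 1) || any(s[, 2] > shape[2]))
    stop("configuration error: coil surface lies outside the image bounds")
  surf_mm <- cbind((s[, 1] - 1) * spacing[1], (s[, 2] - 1) * spacing[2])
  pr <- matrix(((seq_len(shape[1])) - 1) * spacing[1], shape[1], shape[2])
  pc <- matrix(((seq_len(shape[2])) - 1) * spacing[2], shape[1], shape[2],
               byrow = TRUE)
  matrix(.distToSurface(as.vector(pr), as.vector(pc), surf_mm),
         shape[1], shape[2])
}

#' Default bottom-edge coil placement for an image
#'
#' Convenience constructor placing the coil surface along the full bottom
#' row of an image grid, the usual geometry for an endorectal coil under
#' the prostate in an axial slice.
#'
#' @param shape image dimensions (rows, cols) in pixels.
#' @param coilType "rigid" or "inflatable".
#' @param ... further arguments passed to [coilModel()].
#' @return A [CoilModel-class].
#' @examples
#' bottomEdgeCoil(c(96, 96), "inflatable")
#' @export
bottomEdgeCoil <- function(shape, coilType = "rigid", ...) {
  shape <- as.integer(shape)
  coilModel(coilType,
            surface = rbind(c(shape[1], 1), c(shape[1], shape[2])), ...)
}
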