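#' Rectangular region of interest
#'
#' @param label text label for reports.
#' @param rows,cols inclusive 1-based index ranges (length-2 vectors).
#' @return A region specification usable by the ROI metrics.
#' @examples
#' regionRect("background", c(1, 10), c(1, 10))
#' @export
regionRect <- function(label, rows, cols) {
  structure(list(label = label, rows = as.integer(rows),
                 cols = as.integer(cols)), class = "acerRegion")
}

# region -> values; accepts an acerRegion or a logical mask
.regionValues <- function(img, region) {
  V <- if (is(img, "MagnitudeImage")) img@data else as.matrix(img)
  if (inherits(region, "acerRegion")) {
    if (any(region$rows < 1L) || region$rows[2] > nrow(V) ||
        any(region$cols < 1L) || region$cols[2] > ncol(V))
      stop("region '", region$label, "' exceeds the image bounds")
    as.vector(V[region$rows[1]:region$rows[2],
                region$cols[1]:region$cols[2]])
  } else {
    region <- as.matrix(region)
    if (!identical(dim(region), dim(V)))
      stop("region mask must match the image dimensions")
    if (!any(region)) stop("empty region mask")
    V[region]
  }
}

#' Region SNR in decibels
#'
#' The clinical ROI signal-to-noise ratio
#' \eqn{SNR = 20\log_{10}(\bar x / \sigma)}, with \eqn{\bar x} and
#' \eqn{\sigma} the sample mean and standard deviation (n-1 convention)
#' over the region. Invariant to global positive rescaling.
#'
#' @param img image (matrix or [MagnitudeImage-class]).
#' @param region an [regionRect()] or logical mask.
#' @return SNR in dB.
#' @examples
#' snrDb(matrix(c(10, 10, 14, 14), 2), regionRect("r", c(1, 2), c(1, 2)))
#' @export
snrDb <- function(img, region) {
  x <- .regionValues(img, region)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("undefined metric: region standard deviation is zero")
  20 * log10(mean(x) / s)
}

#' Region CNR in decibels
#'
#' Contrast-to-noise ratio between two regions,
#' \eqn{CNR = 20\log_{10}(|\bar x_A - \bar x_B| / \sigma)}, where
#' \eqn{\sigma} is the standard deviation of the background region
#' (`regionA`) only, as the better indicator of the noise process.
#'
#' @param img image (matrix or [MagnitudeImage-class]).
#' @param regionA background region (supplies \eqn{\sigma}).
#' @param regionB contrast region.
#' @return CNR in dB.
#' @export
cnrDb <- function(img, regionA, regionB) {
  a <- .regionValues(img, regionA)
  b <- .regionValues(img, regionB)
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0)
    stop("undefined metric: background standard deviation is zero")
  dm <- abs(mean(a) - mean(b))
  if (dm == 0) stop("undefined metric: regions have equal means")
  20 * log10(dm / s)
}

# 3x3 four-neighbour Laplacian with mirror padding
.laplacian <- function(V) {
  Vp <- .padMirror(V, 1L)
  n <- nrow(V); m <- ncol(V)
  ri <- 2:(n + 1); ci <- 2:(m + 1)
  Vp[ri - 1, ci] + Vp[ri + 1, ci] + Vp[ri, ci - 1] + Vp[ri, ci + 1] -
    4 * Vp[ri, ci]
}

#' Edge preservation
#'
#' Degree to which a reconstruction retains the edge structure of the
#' input: the normalised correlation of the mean-centred 3x3 Laplacians of
#' the two images,
#' \deqn{\Upsilon = \frac{\sum (\nabla^2 V - \overline{\nabla^2 V})
#'   (\nabla^2 \hat G - \overline{\nabla^2 \hat G})}
#'   {\sqrt{\sum (\nabla^2 V - \overline{\nabla^2 V})^2
#'    \sum (\nabla^2 \hat G - \overline{\nabla^2 \hat G})^2}},}
#' evaluated over the mask pixels only (typically the prostate gland,
#' where detail matters and SNR is high). Perfect preservation gives
#' \eqn{\Upsilon = 1}; the metric is invariant to adding constants and to
#' common positive rescaling, and always lies in \[-1, 1\]. Means are
#' taken over the evaluation mask; borders use mirror padding.
#'
#' @param V input image.
#' @param Ghat reconstruction, same shape.
#' @param mask logical matrix or [regionRect()]; default whole image.
#' @return \eqn{\Upsilon \in [-1, 1]}.
#' @examples
#' V <- matrix(runif(64), 8, 8)
#' edgePreservation(V, V)   # exactly 1
#' @export
edgePreservation <- function(V, Ghat, mask = NULL) {
  V <- if (is(V, "MagnitudeImage")) V@data else as.matrix(V)
  G <- if (is(Ghat, "MagnitudeImage")) Ghat@data else as.matrix(Ghat)
  if (!identical(dim(V), dim(G))) stop("images must have the same shape")
  if (is.null(mask)) {
    sel <- rep(TRUE, length(V))
  } else if (inherits(mask, "acerRegion")) {
    sel <- matrix(FALSE, nrow(V), ncol(V))
    sel[mask$rows[1]:mask$rows[2], mask$cols[1]:mask$cols[2]] <- TRUE
  } else {
    sel <- as.matrix(mask)
    if (!identical(dim(sel), dim(V))) stop("mask must match the image")
  }
  lv <- .laplacian(V)[sel]
  lg <- .laplacian(G)[sel]
  lv <- lv - mean(lv); lg <- lg - mean(lg)
  den <- sqrt(sum(lv^2) * sum(lg^2))
  if (den == 0)
    stop("undefined metric: Laplacian constant within the mask")
  sum(lv * lg) / den
}

#' Rank sum of subjective scores
#'
#' Total of all scores given by all evaluators over all slices for one
#' criterion, \eqn{S_R = \sum_i \sum_j S_{ij}}. Higher totals mean the
#' panel judged the criterion better overall.
#'
#' @param table a [ScoreTable-class].
#' @param criterion criterion name.
#' @return Integer rank sum.
#' @export
rankSum <- function(table, criterion) {
  stopifnot(is(table, "ScoreTable"))
  df <- table@scores[table@scores$criterion == criterion, , drop = FALSE]
  if (nrow(df) == 0L) stop("no scores for criterion '", criterion, "'")
  full <- expand.grid(evaluator = unique(df$evaluator),
                      slice = unique(df$slice))
  have <- paste(df$evaluator, df$slice)
  if (!all(paste(full$evaluator, full$slice) %in% have))
    stop("incomplete score table: missing evaluator x slice cells")
  sum(df$score)
}

#' F-pseudosigma of ordinal scores
#'
#' Robust spread measure \eqn{F_\sigma = IQR / 1.349}, comparable to a
#' standard deviation for normal data; 0 means unanimous agreement. The
#' IQR uses the linear-interpolation quantile convention
#' (`stats::quantile` type 7), fixed for reproducibility.
#'
#' @param scores numeric vector of scores.
#' @return Non-negative spread value.
#' @examples
#' fPseudosigma(c(3, 3, 3))      # 0: unanimous
#' fPseudosigma(c(2, 3, 3, 4))   # IQR 1 -> 0.7413
#' @export
fPseudosigma <- function(scores) {
  if (length(scores) < 1L) stop("need at least one score")
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  (q[2] - q[1]) / 1.349
}

#' Median subjective score
#'
#' @param scores numeric vector of scores.
#' @return The median (mean of the middle two for even n).
#' @export
medianScore <- function(scores) {
  if (length(scores) < 1L) stop("need at least one score")
  stats::median(scores)
}

#' Paired two-tailed z test
#'
#' Significance of the mean paired difference between two per-case metric
#' lists under a two-tailed normal reference:
#' \eqn{z = \bar d / (s_d / \sqrt n)} on the paired differences, with the
#' p-value the two-tailed normal tail probability. The 0.05 significance
#' threshold is the caller's concern.
#'
#' @param metricA,metricB equal-length per-case metric values.
#' @return p-value in (0, 1).
#' @examples
#' pairedTwoTailedPValue(c(27.0, 27.3, 27.2), c(26.1, 25.7, 26.7))
#' @export
pairedTwoTailedPValue <- function(metricA, metricB) {
  if (length(metricA) != length(metricB))
    stop("paired lists must have equal length")
  if (length(metricA) < 2L) stop("need at least two pairs")
  d <- metricA - metricB
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0)
    stop("degenerate data: paired differences have zero variance")
  z <- mean(d) / (s / sqrt(length(d)))
  2 * stats::pnorm(-abs(z))
}
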