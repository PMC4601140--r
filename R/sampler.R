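#' Neighbourhood acceptance probability
#'
#' Probability that the neighbourhood of a candidate pixel is a realisation
#' of the same underlying signal as the neighbourhood of the pixel of
#' interest, under the spatially-adaptive Rician model. With candidate
#' patch \eqn{h_k}, reference patch \eqn{h_0}, patch size \eqn{M} and
#' local scale \eqn{\hat\Phi(s_0)}:
#' \deqn{\alpha(s_k \mid s_0) = \min\!\left(1,\
#'   \exp\Big[\tfrac{1}{M}\textstyle\sum_j \big(
#'   \log f(h_k[j] \mid h_0[j], \hat\Phi(s_0))
#'   - \log f(h_0[j] \mid h_0[j], \hat\Phi(s_0))\big)\Big]\right),}
#' the geometric mean over the patch of the per-pixel Rician likelihood
#' ratios, each normalised by its self-likelihood so that a duplicate
#' neighbourhood scores exactly 1. The geometric mean keeps the
#' probability on a patch-size-free scale: a raw product of M likelihood
#' ratios concentrates around \eqn{e^{-M}} even for patches of identical
#' underlying signal, which would reject essentially every candidate.
#' All products are carried in log space; the clip to 1 enforces the
#' probability contract (the Rician mode is not exactly at \eqn{\nu}).
#'
#' @param hk candidate patch values (vector, or matrix with one candidate
#'   per column).
#' @param h0 reference patch values, same patch length.
#' @param phi0 local Rician scale \eqn{\hat\Phi(s_0) > 0}.
#' @return Acceptance probabilities in \[0, 1\], one per candidate.
#' @examples
#' acceptanceProbability(c(10, 10, 10), c(10, 10, 10), phi0 = 2)  # exactly 1
#' acceptanceProbability(c(15), c(12), phi0 = 3)
#' @export
acceptanceProbability <- function(hk, h0, phi0) {
  if (length(phi0) != 1L || !is.finite(phi0) || phi0 <= 0)
    stop("invalid parameter: 'phi0' must be a single positive value")
  nh <- if (is.matrix(hk)) nrow(hk) else length(hk)
  if (nh != length(h0)) stop("patch length mismatch")
  a <- pmin(1, exp(.ricianLogRatio(hk, h0, phi0)))
  if (any(is.nan(a))) stop("acceptance probability is non-finite")
  a
}

# Precomputed geometry shared by drawSamples and acerReconstruct:
# mirror-padded image, linear patch offsets, window offset grid.
.sampleContext <- function(V, cfg) {
  p <- cfg@patchRadius
  Vpad <- .padMirror(V, p)
  nrp <- nrow(Vpad)
  po <- seq.int(-p, p)
  doffs <- as.vector(outer(po, po * nrp, "+"))           # patch offsets
  wo <- seq.int(-cfg@searchRadius, cfg@searchRadius)
  list(V = V, Vpad = Vpad, nrp = nrp, pad = p, doffs = doffs,
       wdr = rep(wo, times = length(wo)),
       wdc = rep(wo, each = length(wo)))
}

# Sample one pixel: returns accepted locations (rows, cols), weights and
# values. Centre always included with weight 1. Candidate locations
# (uniform without replacement over the clipped search window) and
# acceptance variates are pre-drawn, then scanned in draw order until N
# accepted -- equivalent to the sequential accept/reject loop because
# selection never depends on acceptance outcomes. Caller controls RNG.
.samplePixel <- function(ctx, r, c, phi0, cfg) {
  n <- nrow(ctx$V); m <- ncol(ctx$V)
  rr <- r + ctx$wdr; cc <- c + ctx$wdc
  keep <- rr >= 1L & rr <= n & cc >= 1L & cc <= m & !(rr == r & cc == c)
  rr <- rr[keep]; cc <- cc[keep]
  nDraw <- min(cfg@maxDraws, length(rr))
  need <- cfg@nAccept - 1L                      # centre counts towards N
  if (need == 0L || nDraw == 0L)
    return(list(r = r, c = c, w = 1, v = ctx$V[r, c]))
  ord <- sample.int(length(rr), nDraw)
  u <- if (cfg@forceAccept) numeric(nDraw) else stats::runif(nDraw)
  rs <- rr[ord]; cs <- cc[ord]
  candLin <- (cs + ctx$pad - 1L) * ctx$nrp + rs + ctx$pad
  H <- matrix(ctx$Vpad[outer(ctx$doffs, candLin, "+")],
              length(ctx$doffs), nDraw)
  h0 <- ctx$Vpad[(c + ctx$pad - 1L) * ctx$nrp + r + ctx$pad + ctx$doffs]
  alpha <- pmin(1, exp(.ricianLogRatio(H, h0, phi0)))
  if (any(is.nan(alpha))) stop("acceptance probability is non-finite")
  sel <- which(u <= alpha & alpha > 0)
  if (length(sel) > need) sel <- sel[seq_len(need)]
  list(r = c(r, rs[sel]), c = c(c, cs[sel]),
       w = c(1, alpha[sel]), v = c(ctx$V[r, c], ctx$V[cbind(rs[sel], cs[sel])]))
}

#' Draw importance-weighted Monte Carlo samples at one pixel
#'
#' Runs the accept/reject sampler at a single pixel of interest:
#' candidates are drawn uniformly without replacement from the search
#' window (clipped to the image) and accepted when a uniform variate falls
#' below [acceptanceProbability()] computed with the local scale
#' \eqn{\hat\Phi(s_0)}. Sampling stops once `nAccept` samples are
#' accepted (the centre pixel always belongs to the set with weight 1) or
#' the draw budget is exhausted. Patches crossing the image boundary are
#' mirror-padded. Identical configurations (including the seed) yield
#' identical sample sets; the per-pixel random substream is derived from
#' `cfg@seed` and the pixel index, so results do not depend on the order
#' pixels are visited in.
#'
#' @param V a [MagnitudeImage-class] (or matrix).
#' @param s0 integer(2), (row, col) of the pixel of interest, 1-based.
#' @param field a [NoiseScaleField-class] for `V`, or a single scale value
#'   used directly as \eqn{\hat\Phi(s_0)}.
#' @param cfg a [SamplerConfig-class].
#' @return A [SampleSet-class].
#' @examples
#' V <- matrix(10 + rnorm(32 * 32), 32, 32)
#' ss <- drawSamples(abs(V), c(16, 16), field = 1, cfg = samplerConfig(seed = 3))
#' length(ss)
#' @export
drawSamples <- function(V, s0, field, cfg) {
  V <- .asImage(V)
  stopifnot(is(cfg, "SamplerConfig"))
  s0 <- as.integer(s0)
  n <- nrow(V@data); m <- ncol(V@data)
  if (s0[1] < 1L || s0[1] > n || s0[2] < 1L || s0[2] > m)
    stop("'s0' lies outside the image")
  phi0 <- if (is(field, "NoiseScaleField")) field@phi[s0[1], s0[2]]
          else as.numeric(field)
  ctx <- .sampleContext(V@data, cfg)
  res <- .withPreservedRNG({
    set.seed(.pixelSeed(cfg@seed, (s0[2] - 1L) * n + s0[1]))
    .samplePixel(ctx, s0[1], s0[2], phi0, cfg)
  })
  new("SampleSet", center = s0,
      locations = cbind(as.integer(res$r), as.integer(res$c)),
      weights = res$w, values = res$v)
}

#' Weighted-histogram posterior estimate
#'
#' Turns a [SampleSet-class] into the nonparametric posterior of the
#' noise-free intensity: a point mass at each accepted sample value with
#' mass proportional to its acceptance weight,
#' \deqn{\hat p(G(s) \mid V(s)) = \frac{\sum_{j \in \Omega}
#'   \alpha(s_j \mid s_0)\,\delta(G(s) - V(s_j))}{Z},\qquad
#'   Z = \sum_{j \in \Omega} \alpha(s_j \mid s_0).}
#' Masses at coincident values are merged; the masses sum to 1 within
#' 1e-12.
#'
#' @param samples a [SampleSet-class].
#' @return A [PosteriorEstimate-class].
#' @examples
#' V <- matrix(abs(rnorm(64, 20)), 8, 8)
#' ss <- drawSamples(V, c(4, 4), field = 1,
#'                   cfg = samplerConfig(1, 3, 8, seed = 1))
#' posteriorEstimate(ss)
#' @export
posteriorEstimate <- function(samples) {
  stopifnot(is(samples, "SampleSet"))
  Z <- sum(samples@weights)
  if (Z <= 0) stop("all-zero weights: posterior undefined")
  agg <- tapply(samples@weights, samples@values, sum)
  support <- as.numeric(names(agg))
  mass <- as.numeric(agg) / Z
  mass <- mass / sum(mass)                     # exact renormalisation
  new("PosteriorEstimate", support = support, mass = mass, Z = Z)
}

#' Bayesian least-squares (posterior mean) estimate
#'
#' The reconstruction at a pixel is the mean of the posterior estimate,
#' the minimiser of the expected squared reconstruction error. Always a
#' convex combination of the support values.
#'
#' @param posterior a [PosteriorEstimate-class].
#' @return The posterior mean intensity.
#' @examples
#' p <- new("PosteriorEstimate", support = c(10, 20), mass = c(0.25, 0.75),
#'          Z = 0.8)
#' blsEstimate(p)   # 17.5
#' @export
blsEstimate <- function(posterior) {
  stopifnot(is(posterior, "PosteriorEstimate"))
  sum(posterior@support * posterior@mass)
}
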