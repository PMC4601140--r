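---
title: "Noise compensation for coil intensity corrected endorectal MRI: model and methods"
author: "acer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise compensation for coil intensity corrected endorectal MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acer)
```

## The problem

Endorectal receiver coils (ERCs) sit millimetres from the prostate and
buy a large signal-to-noise advantage, but their sensitivity is strongly
inhomogeneous: tissue near the coil is bright, the anterior gland dim.
Scanners correct this with pre-calibration schemes (PURE, Prescan
Normalize, CLEAR, NATURAL): a calibration scan estimates the coil
sensitivity field $B(s)$ and the acquired image is divided by it. The
signal becomes uniform — but the noise, which was stationary in the raw
acquisition, is divided too. Background noise therefore *grows* with
distance from the coil, and in retrospective data only this corrected
image survives; the raw data is gone.

`acer` implements Adaptive Coil Enhancement Reconstruction (ACER), a
post-processing noise compensation method designed for exactly this
situation. It treats the corrected image $V$ as

$$V(s) = G(s) + N(s),$$

with $G$ the noise-free image and $N$ non-stationary noise, and
reconstructs $\hat G(s)$ as the Bayesian least-squares (BLS) estimate,
i.e. the mean of the per-pixel posterior $p(G(s) \mid V(s))$, estimated
by spatially-adaptive importance-weighted Monte Carlo sampling under a
Rician model whose scale varies with the coil SNR profile.

## The noise model

MR magnitude data follows the Rician distribution

$$f(x \mid \nu, \Phi) = \frac{x}{\Phi^2}
  \exp\!\left(-\frac{x^2+\nu^2}{2\Phi^2}\right)
  I_0\!\left(\frac{x\nu}{\Phi^2}\right),$$

which is Rayleigh in background ($\nu = 0$) and close to Gaussian at
high SNR. After division by the sensitivity field, the scale becomes
spatially dependent. We model the coil's SNR depth profile with a
four-parameter family,

$$\gamma(d) = g_f + (A - g_f)\,e^{-d/\tau} \quad (d \le d_{cut}), \qquad
  \gamma(d) = g_f \quad (d > d_{cut}),$$

an exponential decay from the surface gain $A$ toward a floor $g_f$,
with a final abrupt drop at $d_{cut}$. Published depth profiles for
rigid ERCs show a 3–5-fold surface gain, still 1.5–3-fold in the
peripheral zone and only a fraction in the central gland; inflatable
coils respond more weakly. The defaults are:

| parameter | rigid | inflatable | units | meaning |
|---|---|---|---|---|
| `surfaceGain` ($A$) | 5 | 2 | – | gain at the coil surface |
| `decayLength` ($\tau$) | 20 | 20 | mm | e-folding depth |
| `cutoffDistance` ($d_{cut}$) | 60 | 60 | mm | abrupt-drop location |
| `floorGain` ($g_f$) | 1 | 1 | – | gain beyond the cutoff |

The inflatable default deserves a flag: the literature describes a
"1-fold improvement" at an inflatable coil surface, which is ambiguous
between *no* gain and a *doubling*. We default to $A = 2$ (a doubling)
so that the profile stays informative; users with measured profiles for
their coil should override it.

Because correction divides by the sensitivity, the corrected-image noise
scale is

$$\Phi(s) = \Phi_0 / \gamma(d(s)),$$

with $\Phi_0$ the raw acquisition noise level and $d(s)$ the distance
from pixel $s$ to the coil surface (a point or segment in the image,
distances in mm via the pixel spacing).

## Fitting the scale field

`fitScaleField()` estimates $\Phi_0$ from the image itself:

1. Local Rayleigh maximum-likelihood scale estimates on sliding windows
   (default $17\times17$, at least 25 samples each) centred on a
   decimated grid (stride = window radius, for tractability), using
   $\nu \equiv 0$ — the pure-noise model, valid in structure-free
   background. Supply a background mask whenever the image contains
   signal; without one every pixel is used and signal regions inflate
   the estimate.
2. A slope-one least-squares fit of $\log\hat\Phi_{loc}$ against
   $-\log\gamma(d)$; the intercept is $\log\Phi_0$.
3. The dense analytic field $\Phi(s) = \Phi_0/\gamma(d(s))$.

The maximum-likelihood search (`ricianMLScale()`) is one-dimensional in
$\log\Phi$ over the bracket $[10^{-3}s, 10^{3}s]$, $s$ the
root-mean-square of the data, with `optimize()` at tolerance $10^{-9}$
on the log scale — well below the $10^{-6}$ relative agreement we
require against the Rayleigh closed form
$\hat\Phi^2 = \sum x_i^2 / (2n)$. The bracket and tolerance are package
choices; nothing in the underlying method constrains them. Joint
estimation of $\nu$ and bias-corrected moment estimators are
deliberately out of scope.

## The Monte Carlo posterior

At each pixel $s_0$, candidates $s_k$ are drawn uniformly without
replacement from a search window $\eta$ (clipped to the image), and each
is accepted with probability

$$\alpha(s_k \mid s_0) = \min\!\left(1, \exp\Big[\frac{1}{M}
  \sum_{j=1}^{M}\big(\log f(h_k[j] \mid h_0[j], \hat\Phi(s_0))
  - \log f(h_0[j] \mid h_0[j], \hat\Phi(s_0))\big)\Big]\right),$$

where $h_k$, $h_0$ are the $M$-pixel neighbourhoods of $s_k$ and $s_0$
and the location parameter of each factor is the observed centre patch
value $\nu(j) = h_0[j]$, taken literally with no pre-smoothing. Accepted
samples form the weighted-histogram posterior

$$\hat p(G(s)\mid V(s)) = \frac{\sum_{j\in\Omega} \alpha(s_j \mid s_0)\,
  \delta(G(s) - V(s_j))}{Z},$$

and the reconstruction is its mean — a convex combination of observed
values, so the output can never leave the observed intensity range.

**Why the $1/M$ exponent.** The normaliser in the acceptance ratio is
specified only through its contract: duplicate neighbourhoods must score
exactly 1. Normalising each factor by its self-likelihood
$f(h_0[j] \mid h_0[j], \hat\Phi)$ achieves that, but the *raw product*
of $M$ such ratios concentrates around $e^{-M}$ even when the two
patches carry identical underlying signal (each noisy factor contributes
about $-1$ in log-expectation). With 49-pixel patches that is
$\alpha \approx 10^{-21}$: no candidate would ever be accepted and the
reconstruction would collapse to the identity. We therefore use the
geometric mean of the per-pixel ratios — the same statistic on a
patch-size-free scale. The duplicate contract, the clip at 1, and every
single-pixel identity are unchanged; homogeneous-region acceptance lands
near $e^{-1}$, which is what makes the sampler productive. This is the
package's central design decision.

Other sampler choices:

* **Instrumental distribution**: uniform over the clipped window,
  without replacement. Candidate locations and acceptance variates are
  pre-drawn and scanned in draw order until $N$ accepted — equivalent to
  the sequential loop, since selection never depends on acceptance
  outcomes.
* **Defaults**: patch radius 3 ($7\times7$), search radius 10
  ($21\times21$), $N = 32$ accepted samples (the centre counts),
  `maxDraws` $= 4N$. The method's source material fixes none of these;
  the defaults balance detail preservation against smoothing at
  clinically typical spacings (0.3–0.8 mm).
* **Centre handling**: $s_0$ always enters $\Omega$ with weight 1, so
  the estimator is defined even if everything else is rejected. The
  patch product runs over *all* patch pixels, centre included.
* **Boundaries**: mirror padding (edge duplicated) for patch
  extraction; candidate locations themselves are real image pixels.
* **Reproducibility**: each pixel derives its own RNG substream from the
  configured seed and the pixel's linear index, so results are exactly
  reproducible and independent of processing order. No tie-breaking is
  needed — weights are continuous.
* **Degenerate inputs**: a zero-valued patch pixel contributes a
  vanishing density; exact value duplicates short-circuit to a zero
  log-ratio so that $0/0$ cases cannot poison the product. Acceptance
  probabilities that still evaluate non-finite raise an error rather
  than being silently dropped.

`ricianLogPdf()` keeps every product in log space, with the Bessel term
in exponentially-scaled form $\log I_0(z) = \log(\mathrm{i0e}(z)) + z$.
Since R's `besselI` costs $O(z)$, arguments beyond $z = 50$ use the
uniform asymptotic expansion of $I_0$ (four correction terms; the two
branches agree to about $10^{-10}$ at the switch point, and arguments of
$10^6$ and beyond remain finite and cheap).

## The synthetic phantom

`phantomSpec()` / `makePhantom()` build a piecewise-constant digital
phantom modelled on commercial prostate training phantoms: a
$5.0\times4.5$ cm gland ellipse, three hypointense lesions of radius
2.5–5 mm, a 7 mm urethra, in a signal-free background, rasterised at
0.3 mm on $256\times256$ by default (geometry scales with the field of
view, so the canonical $96\times96$ / 0.8 mm test fixture keeps the same
anatomy). Intensities default to prostate 200, lesion 120, urethra 60,
background 0 — T2-like contrast on an arbitrary scale. The background is
deliberately signal-free so that background pixels are pure Rayleigh
noise, which is both what the scale-field fit assumes and how
structure-free SNR regions are chosen in practice.

`simulateAcquisition()` multiplies the ground truth by the sensitivity
field (taken equal to the SNR profile $\gamma$ — only the ratio
structure matters to the method), adds two independent Gaussian noise
channels of standard deviation $\sigma_0$ (default 10, i.e. raw
background SNR 20:1 against the gland), and returns the magnitude:
Rician with stationary scale.  `applyPrecalibrationCorrection()` then
divides by the known sensitivity, exactly as an idealised PURE-style
correction would — producing noise that grows with distance from the
coil. Calibration-scan noise is not modelled.

What the simulator does *not* emulate: partial-volume edges, tissue
texture, bias-field estimation error, k-space artefacts, or the cropped
cushion noise band seen in physical phantom scans. Tests passing on this
phantom therefore establish the estimator's statistical behaviour under
its stated noise model, not clinical image quality.

## Evaluation metrics

* `snrDb()` / `cnrDb()`: ROI metrics in decibels,
  $20\log_{10}(\bar x/\sigma)$ and
  $20\log_{10}(|\bar x_A - \bar x_B|/\sigma_A)$, with the *sample*
  (n−1) standard deviation — the usual clinical ROI practice leaves the
  convention unstated, so it is fixed and documented here.
* `edgePreservation()`: the normalised correlation of mean-centred
  $3\times3$ four-neighbour Laplacians, masked to the region where
  detail matters (typically the gland). The neighbourhood over which the
  Laplacian means are taken is interpreted as the whole evaluation mask,
  which makes the metric a masked Pearson correlation of Laplacians and
  yields the exact identity $\Upsilon(V, V) = 1$.
* Reader-score summaries: `rankSum()`, `medianScore()`,
  `fPseudosigma()` ($IQR/1.349$, quantile type 7 — the linear
  interpolation convention, fixed for reproducibility).
* `pairedTwoTailedPValue()`: the "two-tailed normal" significance test
  is realised as a paired z test on per-case differences; the exact
  construction is an interpretation and is labelled as such.

## Coordinate conventions

Inside R everything is 1-based (row, column), matrix order, distances in
mm via the pixel spacing. Interchange files — coil configs, region
JSON — use 0-based row-major indices, converted at the IO boundary.
DICOM input is not supported; NIfTI is the primary format, with PNG and
TIFF (sidecar-scaled) for fixtures and previews. Volumes are processed
slice by slice, never implicitly.

## Problem sizes and runtime

The shipped tests validate parameter recovery on $256\times256$ phantoms
($\sigma_0 \in \{2, 5, 10\}$, both coil types, three seeds each,
recovery within 10%) and run the full reconstruction on the canonical
$96\times96$ fixture, which takes on the order of ten seconds on one
core; a $256\times256$ slice at default settings takes a few minutes.
The exhaustive-window brute-force equivalence uses an $8\times8$ image
where every candidate can be enumerated.

## Known limitations

* 2-D only; no volumetric sampling, multi-coil combination, or
  iterated/multi-pass reconstruction.
* The coil profile is a qualitative parametric family; per-vendor
  measured profiles should replace the defaults where available.
* $\Phi_0$ estimation needs structure-free background; heavily cropped
  images without background will mis-fit unless a field is supplied
  directly.
* The BLS estimate draws only from observed intensities in the search
  window; it cannot synthesise values absent from the neighbourhood.
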