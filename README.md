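# acer

Monte Carlo noise compensation for coil intensity corrected endorectal
MRI.

## The problem

Endorectal coils (ERCs) give prostate MRI a large but spatially
inhomogeneous SNR boost: bright at the peripheral zone next to the coil,
dim in the anterior gland. Scanner-side pre-calibration correction
(PURE, Prescan Normalize, CLEAR, NATURAL) divides the image by a coil
sensitivity estimate to uniformise the signal — and in doing so divides
the noise too, so background noise *grows* with distance from the coil.
In retrospective studies only this corrected image is available; the raw
data is gone.

`acer` is for researchers working with such corrected endorectal images
(or simulations of them) who want to suppress the amplified noise while
keeping prostatic detail, and for method developers who need a fully
seeded synthetic testbed for non-stationary Rician denoising.

## The method

The corrected image is modelled as `V(s) = G(s) + N(s)` with
non-stationary Rician noise: the magnitude density is

    f(x | nu, Phi) = x/Phi^2 * exp(-(x^2 + nu^2)/(2 Phi^2)) * I0(x nu / Phi^2)

and the per-pixel scale follows the coil's SNR depth profile,
`Phi(s) = Phi0 / gamma(d(s))`, with
`gamma(d) = g_f + (A - g_f) exp(-d/tau)` up to a cutoff distance
(rigid coils: surface gain A ≈ 5; inflatable: A ≈ 2). `Phi0` is fitted
from background windows by Rayleigh maximum likelihood.

Adaptive Coil Enhancement Reconstruction (ACER) then estimates each
pixel's posterior `p(G(s) | V(s))` by importance-weighted Monte Carlo
sampling: candidate pixels from a search window are accepted with
probability equal to the (geometric-mean, self-likelihood-normalised)
Rician likelihood ratio of their neighbourhoods at the local scale
`Phi(s0)`, and the reconstruction is the Bayesian least-squares estimate
— the mean of the weighted-histogram posterior. Duplicate
neighbourhoods are accepted with probability exactly 1; the output never
leaves the observed intensity range; everything is reproducible from a
single seed.

The package also implements the matching evaluation suite — ROI SNR and
CNR in decibels, Laplacian edge preservation, rank-sum / median /
F-pseudosigma summaries of ordinal reader scores, paired two-tailed
z tests — and a seeded prostate-phantom simulator that reproduces the
noise structure of pre-calibration corrected acquisitions. See the
methods vignette (`vignettes/acer-methods.Rmd`) for the model, the
design decisions and their rationale.

## Worked example

```r
library(acer)

## canonical seeded fixture: ground truth G, corrected acquisition V
fix <- makeFixtureSuite(tempfile(), seed = 42)
V <- fix$corrected; G <- fix$groundTruth

## fit the non-stationary noise scale from the background
field <- fitScaleField(V, fix$coil, backgroundMask = imageData(G) == 0)
field
#> NoiseScaleField: 96 x 96, base scale Phi0 = 10
#>   Phi range [2, 10]

## reconstruct and evaluate
Ghat <- acerReconstruct(V, fix$coil, samplerConfig(seed = 42), field = field)
snrDb(V, fix$regions$background); snrDb(Ghat, fix$regions$background)
```

Output on this fixture (simulated with raw noise sigma0 = 10, rigid
coil, surface gain 5):

```
background SNR: 5.6 dB -> 20.7 dB
CNR:            29.1 dB -> 44.2 dB
RMSE vs truth:  9.12 -> 8.06
edge preservation (gland): 0.985
```

The fitted base scale (10.0) recovers the simulated raw noise level; the
background SNR and the background–prostate CNR rise sharply because the
compensation is strongest where the corrected noise is largest (far from
the coil), while edge preservation within the gland stays near 1,
i.e. prostatic structure is retained.

A thin command-line front end wraps the same functions:

```sh
inst/exec/acer simulate --out-dir fix --shape 96 --sigma0 10 --seed 42
inst/exec/acer denoise  --input fix/corrected.nii --output fix/acer.nii \
                        --coil-config fix/coil.yaml --seed 42
inst/exec/acer metrics  --input fix/acer.nii --regions fix/regions.json
inst/exec/acer scores   --table scores.csv
```

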