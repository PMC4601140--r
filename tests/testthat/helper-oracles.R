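# Independent reference implementations used as oracles. Deliberately
# plain (loops, direct formulas) and kept separate from the package code
# paths they check.

# Rician density by direct evaluation of the textbook formula
refRicianPdf <- function(x, nu, phi) {
  (x / phi^2) * exp(-(x^2 + nu^2) / (2 * phi^2)) *
    besselI(x * nu / phi^2, 0)
}

# mirror reflection of an index into 1..n (edge duplicated)
refMirror <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# patch around (r, c) as a vector, mirror-padded, radius h
refPatch <- function(V, r, c, h) {
  out <- numeric((2 * h + 1)^2)
  k <- 0L
  for (dc in -h:h) for (dr in -h:h) {
    k <- k + 1L
    out[k] <- V[refMirror(r + dr, nrow(V)), refMirror(c + dc, ncol(V))]
  }
  out
}

# acceptance weight: geometric mean over the patch of the per-pixel
# likelihood ratios f(hk | h0, phi) / f(h0 | h0, phi), clipped to 1
refAlpha <- function(hk, h0, phi) {
  lr <- 0
  for (j in seq_along(h0)) {
    if (hk[j] == h0[j]) next
    lr <- lr + log(refRicianPdf(hk[j], h0[j], phi)) -
      log(refRicianPdf(h0[j], h0[j], phi))
  }
  min(1, exp(lr / length(h0)))
}

# direct exhaustive weighted-mean reconstruction: all window pixels
# weighted by alpha, no accept/reject loop
refExhaustiveReconstruct <- function(V, phiField, patchRadius) {
  out <- V
  for (r in seq_len(nrow(V))) for (c in seq_len(ncol(V))) {
    h0 <- refPatch(V, r, c, patchRadius)
    num <- V[r, c]; den <- 1
    for (rr in seq_len(nrow(V))) for (cc in seq_len(ncol(V))) {
      if (rr == r && cc == c) next
      a <- refAlpha(refPatch(V, rr, cc, patchRadius), h0, phiField[r, c])
      num <- num + a * V[rr, cc]
      den <- den + a
    }
    out[r, c] <- num / den
  }
  out
}

rmse <- function(a, b) {
  if (is(a, "MagnitudeImage")) a <- imageData(a)
  if (is(b, "MagnitudeImage")) b <- imageData(b)
  sqrt(mean((a - b)^2))
}

# seeded Rayleigh / Rician draws for estimator tests
rRician <- function(n, nu, phi) {
  sqrt((nu + phi * rnorm(n))^2 + (phi * rnorm(n))^2)
}
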