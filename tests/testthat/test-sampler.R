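test_that("duplicate neighbourhoods are accepted with probability one", {
  set.seed(14)
  for (i in 1:20) {
    h <- rRician(49, runif(1, 0, 30), runif(1, 0.5, 8))
    expect_identical(acceptanceProbability(h, h, runif(1, 0.1, 10)), 1)
  }
})

test_that("acceptance matches direct single-pixel density arithmetic", {
  # one-pixel patches: alpha = min(1, f(15|12,3) / f(12|12,3))
  want <- min(1, refRicianPdf(15, 12, 3) / refRicianPdf(12, 12, 3))
  expect_equal(acceptanceProbability(15, 12, 3), want, tolerance = 1e-12)
  # a deviating pixel cannot beat the self-likelihood cap
  a <- acceptanceProbability(c(10, 10, 10 + 3 * 10), c(10, 10, 10), 3)
  expect_lt(a, 1)
  expect_gt(a, 0)
})

test_that("acceptance agrees with the patch-level reference formula", {
  set.seed(15)
  for (i in 1:10) {
    h0 <- rRician(9, 20, 4)
    hk <- rRician(9, 20, 4)
    expect_equal(acceptanceProbability(hk, h0, 4), refAlpha(hk, h0, 4),
                 tolerance = 1e-10)
  }
})

test_that("acceptance rejects malformed inputs", {
  expect_error(acceptanceProbability(c(1, 2), c(1, 2, 3), 1), "mismatch")
  expect_error(acceptanceProbability(1, 1, 0), "phi0")
})

test_that("constant images accept every draw at full weight", {
  V <- matrix(7, 24, 24)
  cfg <- samplerConfig(patchRadius = 2, searchRadius = 6, nAccept = 16,
                       seed = 2)
  ss <- drawSamples(V, c(12, 12), field = 1.5, cfg = cfg)
  expect_equal(length(ss), 16L)
  expect_equal(sampleWeights(ss), rep(1, 16))
  expect_equal(sampleValues(ss), rep(7, 16))
})

test_that("N = 1 returns the centre-only set with weight one", {
  set.seed(4)
  V <- matrix(rRician(400, 10, 2), 20, 20)
  cfg <- samplerConfig(patchRadius = 1, searchRadius = 4, nAccept = 1,
                       maxDraws = 4, seed = 2)
  ss <- drawSamples(V, c(10, 11), field = 2, cfg = cfg)
  expect_equal(length(ss), 1L)
  expect_equal(sampleLocations(ss), cbind(10L, 11L))
  expect_equal(sampleWeights(ss), 1)
  expect_equal(sampleValues(ss), V[10, 11])
})

test_that("sampling is reproducible under a fixed seed and moves with it", {
  set.seed(8)
  V <- matrix(rRician(32 * 32, 15, 3), 32, 32)
  cfg <- samplerConfig(seed = 123)
  a <- drawSamples(V, c(16, 16), field = 3, cfg = cfg)
  b <- drawSamples(V, c(16, 16), field = 3, cfg = cfg)
  expect_identical(sampleLocations(a), sampleLocations(b))
  expect_identical(sampleWeights(a), sampleWeights(b))
  c2 <- drawSamples(V, c(16, 16), field = 3,
                    cfg = samplerConfig(seed = 124))
  expect_false(identical(sampleLocations(a), sampleLocations(c2)) &&
                 identical(sampleWeights(a), sampleWeights(c2)))
})

test_that("sampling does not disturb the caller's RNG stream", {
  V <- matrix(rRician(100, 10, 2), 10, 10)
  set.seed(99); before <- runif(3)
  set.seed(99)
  invisible(drawSamples(V, c(5, 5), field = 2,
                        cfg = samplerConfig(1, 3, 4, seed = 7)))
  expect_identical(runif(3), before)
})

test_that("posterior masses normalise exactly as hand computations", {
  one <- new("SampleSet", center = c(1L, 1L), locations = cbind(1L, 1L),
             weights = 1, values = 42)
  p <- posteriorEstimate(one)
  expect_equal(p@support, 42); expect_equal(p@mass, 1); expect_equal(p@Z, 1)

  sym <- new("SampleSet", center = c(1L, 1L),
             locations = cbind(c(1L, 2L), c(1L, 1L)),
             weights = c(0.5, 0.5), values = c(10, 20))
  p <- posteriorEstimate(sym)
  expect_equal(p@support, c(10, 20)); expect_equal(p@mass, c(0.5, 0.5))
  expect_equal(p@Z, 1)

  skewed <- new("SampleSet", center = c(1L, 1L),
                locations = cbind(c(1L, 2L), c(1L, 1L)),
                weights = c(0.2, 0.6), values = c(10, 20))
  p <- posteriorEstimate(skewed)
  expect_equal(p@mass, c(0.25, 0.75))
  expect_equal(p@Z, 0.8)
  expect_equal(blsEstimate(p), 17.5)
})

test_that("posterior mean stays inside the sample range", {
  set.seed(31)
  V <- matrix(rRician(24 * 24, 12, 4), 24, 24)
  cfg <- samplerConfig(2, 6, 12, seed = 5)
  for (i in 1:10) {
    px <- sample.int(24, 2)
    ss <- drawSamples(V, px, field = 4, cfg = cfg)
    g <- blsEstimate(posteriorEstimate(ss))
    expect_gte(g, min(sampleValues(ss)))
    expect_lte(g, max(sampleValues(ss)))
  }
})

test_that("reconstruction of a constant image is the identity", {
  V <- matrix(5.5, 32, 32)
  coil <- bottomEdgeCoil(c(32, 32))
  fld <- new("NoiseScaleField", phi = matrix(1, 32, 32), baseScale = 1,
             distance = distanceMap(c(32, 32), 1, coil))
  out <- acerReconstruct(V, coil, samplerConfig(2, 5, 8, seed = 3),
                         field = fld)
  expect_equal(imageData(out), V)
})

test_that("reconstruction respects the observed intensity range and seed", {
  set.seed(17)
  V <- matrix(rRician(32 * 32, 20, 5), 32, 32)
  coil <- bottomEdgeCoil(c(32, 32))
  fld <- new("NoiseScaleField", phi = matrix(5, 32, 32), baseScale = 5,
             distance = distanceMap(c(32, 32), 1, coil))
  cfg <- samplerConfig(2, 5, 8, seed = 21)
  a <- acerReconstruct(V, coil, cfg, field = fld)
  expect_gte(min(imageData(a)), min(V))
  expect_lte(max(imageData(a)), max(V))
  b <- acerReconstruct(V, coil, cfg, field = fld)
  expect_identical(imageData(a), imageData(b))
})

test_that("per-pixel reconstruction equals the drawSamples pipeline", {
  set.seed(23)
  V <- matrix(rRician(28 * 28, 18, 4), 28, 28)
  coil <- bottomEdgeCoil(c(28, 28))
  fld <- new("NoiseScaleField", phi = matrix(4, 28, 28), baseScale = 4,
             distance = distanceMap(c(28, 28), 1, coil))
  cfg <- samplerConfig(seed = 77)
  full <- acerReconstruct(V, coil, cfg, field = fld)
  for (px in list(c(1, 1), c(14, 20), c(28, 28))) {
    g <- blsEstimate(posteriorEstimate(drawSamples(V, px, fld, cfg)))
    expect_equal(imageData(full)[px[1], px[2]], g, tolerance = 1e-12)
  }
})

test_that("exhaustive forced-acceptance run equals brute-force weighted mean", {
  set.seed(41)
  V <- matrix(rRician(64, 10, 2), 8, 8)
  phiField <- matrix(2.5, 8, 8)
  coil <- bottomEdgeCoil(c(8, 8))
  fld <- new("NoiseScaleField", phi = phiField, baseScale = 2.5,
             distance = distanceMap(c(8, 8), 1, coil))
  cfg <- samplerConfig(patchRadius = 1, searchRadius = 8, nAccept = 64,
                       maxDraws = 64, seed = 1, forceAccept = TRUE)
  got <- acerReconstruct(V, coil, cfg, field = fld)
  want <- refExhaustiveReconstruct(V, phiField, patchRadius = 1)
  expect_equal(imageData(got), want, tolerance = 1e-10)
})
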