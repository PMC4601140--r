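test_that("ground truth holds exactly the specified intensity levels", {
  spec <- phantomSpec(shape = c(96, 96), spacing = 0.8)
  G <- imageData(makePhantom(spec))
  expect_setequal(unique(as.vector(G)), c(0, 60, 120, 200))

  noLesion <- phantomSpec(shape = c(96, 96), spacing = 0.8, lesions = 0)
  expect_setequal(unique(as.vector(imageData(makePhantom(noLesion)))),
                  c(0, 60, 200))

  # a lesion centre pixel carries the lesion intensity
  ctr <- spec@lesionCenters[1, ] / spec@spacing + 1
  expect_equal(G[round(ctr[1]), round(ctr[2])], 120)
  # the phantom is deterministic
  expect_identical(G, imageData(makePhantom(spec)))
})

test_that("phantom validity rejects out-of-bound or oversized structures", {
  expect_error(phantomSpec(shape = c(32, 32), spacing = 0.5), "outside")
  spec <- phantomSpec(shape = c(96, 96), spacing = 0.8)
  expect_error(phantomSpec(shape = c(96, 96), spacing = 0.8,
                           lesions = list(centers = rbind(spec@prostateCenter + c(21, 0)),
                                          radii = 2.5)),
               "inside the prostate")
})

test_that("simulated background magnitude is Rayleigh with the right moment", {
  flat <- coilModel("rigid", surface = c(1, 1), surfaceGain = 1,
                    floorGain = 1)
  G <- magnitudeImage(matrix(0, 1000, 1000))
  U <- simulateAcquisition(G, flat, sigma0 = 3, seed = 12)
  # Rayleigh mean: sigma * sqrt(pi / 2)
  expect_equal(mean(imageData(U)), 3 * sqrt(pi / 2), tolerance = 0.01)
  # reproducibility
  U2 <- simulateAcquisition(G, flat, sigma0 = 3, seed = 12)
  expect_identical(imageData(U), imageData(U2))
})

test_that("the noiseless limit reproduces the sensitivity-weighted truth", {
  spec <- phantomSpec(shape = c(64, 64), spacing = 1.2)
  G <- makePhantom(spec)
  coil <- bottomEdgeCoil(dim(G))
  B <- snrGain(distanceMap(dim(G), pixelSpacing(G), coil), coil)
  U <- simulateAcquisition(G, coil, sigma0 = 1e-9, seed = 5)
  expect_equal(imageData(U), B * imageData(G), tolerance = 1e-6)
})

test_that("pre-calibration correction divides out the sensitivity", {
  spec <- phantomSpec(shape = c(64, 64), spacing = 1.2)
  G <- makePhantom(spec)
  flat <- coilModel("rigid", surface = c(1, 1), surfaceGain = 1,
                    floorGain = 1)
  U <- simulateAcquisition(G, flat, sigma0 = 4, seed = 9)
  expect_identical(imageData(applyPrecalibrationCorrection(U, flat)),
                   imageData(U))
  zero <- coilModel("rigid", surface = c(1, 1), floorGain = 0,
                    cutoffDistance = 10)
  expect_error(applyPrecalibrationCorrection(U, zero), "configuration")
})

test_that("corrected noise grows away from the coil as gamma predicts", {
  # noise-only acquisition on a wide grid; with a bottom-edge coil every
  # row sits at a single exact distance, so row-wise stds are clean
  n <- 120; m <- 2000
  coil <- bottomEdgeCoil(c(n, m), "rigid")
  G <- magnitudeImage(matrix(0, n, m), spacing = 1)
  V <- applyPrecalibrationCorrection(
    simulateAcquisition(G, coil, sigma0 = 5, seed = 33), coil)
  dRow <- (n - seq_len(n)) * 1
  near <- which(dRow == 2); far <- which(dRow == 40)
  ratio <- sd(imageData(V)[far, ]) / sd(imageData(V)[near, ])
  expect_equal(ratio, snrGain(2, coil) / snrGain(40, coil), tolerance = 0.05)
})

test_that("corrected signal is unbiased in the high-SNR regime", {
  spec <- phantomSpec(shape = c(256, 256), spacing = 0.3, sigma0 = 5)
  G <- makePhantom(spec)
  coil <- bottomEdgeCoil(dim(G), "rigid")
  V <- applyPrecalibrationCorrection(
    simulateAcquisition(G, coil, spec@sigma0, seed = 8), coil)
  B <- snrGain(distanceMap(dim(G), pixelSpacing(G), coil), coil)
  sel <- imageData(G) == 200 & (B * 200 / spec@sigma0) > 5
  expect_gt(sum(sel), 1000)
  expect_equal(mean(imageData(V)[sel]) / 200, 1, tolerance = 0.02)
})

test_that("fixture suite is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- phantomSpec(shape = c(48, 48), spacing = 1.6, seed = 4)
  r1 <- makeFixtureSuite(d1, seed = 4, spec = spec)
  r2 <- makeFixtureSuite(d2, seed = 4, spec = spec)
  for (nm in names(r1$paths)) {
    expect_identical(unname(tools::md5sum(r1$paths[[nm]])),
                     unname(tools::md5sum(r2$paths[[nm]])),
                     label = paste("md5 of", nm))
  }
  manifest <- jsonlite::read_json(r1$paths$manifest, simplifyVector = TRUE)
  expect_equal(manifest$sigma0, spec@sigma0)
  expect_equal(manifest$coil$surface_gain, 5)
  expect_true(all(c("tau_mm", "d_cut_mm", "floor_gain") %in%
                    names(manifest$coil)))
  # regions must fit the image
  for (r in r1$regions) {
    expect_gte(r$rows[1], 1); expect_lte(r$rows[2], 48)
    expect_gte(r$cols[1], 1); expect_lte(r$cols[2], 48)
    expect_true(r$rows[1] <= r$rows[2] && r$cols[1] <= r$cols[2])
  }
})

test_that("canonical regions isolate pure background and pure gland", {
  spec <- phantomSpec(shape = c(96, 96), spacing = 0.8)
  G <- imageData(makePhantom(spec))
  regs <- phantomRegions(spec)
  bg <- G[regs$background$rows[1]:regs$background$rows[2],
          regs$background$cols[1]:regs$background$cols[2]]
  pro <- G[regs$prostate$rows[1]:regs$prostate$rows[2],
           regs$prostate$cols[1]:regs$prostate$cols[2]]
  expect_true(all(bg == 0))
  expect_true(all(pro == 200))
})
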