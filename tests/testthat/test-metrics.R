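test_that("region SNR matches hand arithmetic and is scale invariant", {
  img <- matrix(c(10, 10, 14, 14), 2, 2)
  reg <- regionRect("r", c(1, 2), c(1, 2))
  # mean 12, sample sd 2.3094: 20*log10(5.1962) = 14.312 dB
  expect_equal(snrDb(img, reg), 20 * log10(12 / sd(c(10, 10, 14, 14))),
               tolerance = 1e-12)
  expect_equal(snrDb(img, reg), 14.3124, tolerance = 1e-4)
  expect_equal(snrDb(3.7 * img, reg), snrDb(img, reg), tolerance = 1e-12)
  expect_error(snrDb(matrix(5, 2, 2), reg), "undefined")
})

test_that("CNR uses the background noise and the absolute contrast", {
  set.seed(2)
  a <- 10 + 2 * scale(rnorm(50))            # mean 10, sd exactly 2
  img <- matrix(c(a, rep(30, 50)), 10, 10)
  regA <- regionRect("bg", c(1, 10), c(1, 5))
  regB <- regionRect("tissue", c(1, 10), c(6, 10))
  expect_equal(cnrDb(img, regA, regB), 20 * log10(20 / 2), tolerance = 1e-9)
  # swapping the means leaves |xA - xB| unchanged
  img2 <- matrix(c(a + 20, rep(10, 50)), 10, 10)
  expect_equal(cnrDb(img2, regA, regB), cnrDb(img, regA, regB),
               tolerance = 1e-9)
  expect_error(cnrDb(img, regA, regA), "undefined")
})

test_that("edge preservation is exactly one for a perfect reconstruction", {
  set.seed(6)
  V <- matrix(runif(64 * 64, 0, 100), 64, 64)
  expect_equal(edgePreservation(V, V), 1, tolerance = 1e-14)
  mask <- matrix(FALSE, 64, 64); mask[10:40, 15:50] <- TRUE
  expect_equal(edgePreservation(V, V, mask), 1, tolerance = 1e-14)
})

test_that("edge preservation is linear in sign and kills constants and gains", {
  set.seed(61)
  V <- matrix(runif(400, 0, 50), 20, 20)
  expect_equal(edgePreservation(V, -V + 60), -1, tolerance = 1e-12)
  expect_equal(edgePreservation(V, V + 17), 1, tolerance = 1e-12)
  expect_equal(edgePreservation(V, 4 * V), 1, tolerance = 1e-12)
  expect_equal(edgePreservation(V + 3, 2 * V + 1), 1, tolerance = 1e-12)
  # bounded by 1 in magnitude for arbitrary pairs
  for (i in 1:10) {
    W <- matrix(runif(400), 20, 20)
    expect_lte(abs(edgePreservation(V, W)), 1 + 1e-12)
  }
  expect_error(edgePreservation(V, matrix(2, 20, 20)), "undefined")
})

test_that("rank sum totals the complete evaluator x slice table", {
  full <- expand.grid(evaluator = 1:7, slice = 1:3)
  full$criterion <- "contrast"; full$score <- 5L
  expect_equal(rankSum(scoreTable(full), "contrast"), 105)

  one <- data.frame(evaluator = 1, slice = 1, criterion = "sharpness",
                    score = 3L)
  expect_equal(rankSum(scoreTable(one), "sharpness"), 3)

  grid <- expand.grid(evaluator = 1:2, slice = 1:2)
  grid$criterion <- "noise"; grid$score <- c(1L, 2L, 3L, 4L)
  expect_equal(rankSum(scoreTable(grid), "noise"), 10)

  expect_error(rankSum(scoreTable(grid[-2, ]), "noise"), "incomplete")
  expect_error(rankSum(scoreTable(grid), "absent"), "no scores")
})

test_that("F-pseudosigma follows IQR / 1.349 with linear interpolation", {
  expect_equal(fPseudosigma(rep(4, 9)), 0)
  expect_equal(fPseudosigma(c(1, 2, 3)), 1 / 1.349, tolerance = 1e-12)
  expect_equal(fPseudosigma(c(1, 2, 3, 4, 5)), 2 / 1.349, tolerance = 1e-12)
  # translation invariance and linear scaling
  s <- c(1, 2, 2, 3, 5)
  expect_equal(fPseudosigma(s + 10), fPseudosigma(s), tolerance = 1e-12)
  expect_equal(fPseudosigma(3 * s), 3 * fPseudosigma(s), tolerance = 1e-12)
})

test_that("median score handles odd and even panels", {
  expect_equal(medianScore(c(1, 2, 3)), 2)
  expect_equal(medianScore(c(3, 3, 4, 4)), 3.5)
  expect_equal(medianScore(5), 5)
})

test_that("paired z test matches an independent normal-CDF computation", {
  set.seed(19)
  d <- rnorm(20)
  a <- rnorm(20, 50, 5); b <- a - d
  z <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(pairedTwoTailedPValue(a, b), 2 * (1 - pnorm(abs(z))),
               tolerance = 1e-12)
  # under the null about 5% of p-values fall below 0.05
  ps <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    x <- rnorm(15); pairedTwoTailedPValue(x, rnorm(15))
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.045)
})

test_that("degenerate paired data is refused", {
  expect_error(pairedTwoTailedPValue(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(pairedTwoTailedPValue(c(2, 3, 4, 5), c(1, 2, 3, 4)),
               "degenerate")
  expect_error(pairedTwoTailedPValue(1, 2), "two pairs")
  expect_error(pairedTwoTailedPValue(c(1, 2), c(1, 2, 3)), "equal length")
})
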