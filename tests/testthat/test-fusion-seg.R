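test_that("overlay limits reduce to pure CT or pure colormapped PET", {
  set.seed(8)
  ct <- Image2D(matrix(runif(64, 0, 100), 8, 8))
  pet <- Image2D(matrix(runif(64), 8, 8))

  f0 <- fuseOverlay(pet, ct, alpha = 0)
  ctNorm <- (pixels(ct) - min(pixels(ct))) / diff(range(pixels(ct)))
  for (ch in 1:3) expect_equal(f0[, , ch], ctNorm)

  f1 <- fuseOverlay(pet, Image2D(matrix(0, 8, 8)), alpha = 1)
  petNorm <- (pixels(pet) - min(pixels(pet))) / diff(range(pixels(pet)))
  expect_equal(f1[, , 1], matrix(pmin(3 * petNorm, 1), 8, 8))

  fh <- fuseOverlay(pet, ct, alpha = 0.5)
  expect_true(all(fh >= 0 & fh <= 1))
  expect_error(fuseOverlay(pet, Image2D(matrix(0, 4, 4))), "dimensions")
})

test_that("high-uptake thresholding matches its definition", {
  expect_identical(
    segmentHighUptake(Image2D(matrix(5, 6, 6)), "fraction_of_max",
                      0.5)@nForeground, 36L)
  onehot <- Image2D(matrix(c(100, rep(0, 63)), 8, 8))
  seg <- segmentHighUptake(onehot, "fraction_of_max", 0.5)
  expect_identical(seg@nForeground, 1L)
  expect_identical(which(seg@mask == 1), 1L)
  segF <- segmentHighUptake(onehot, "fixed", 50)
  expect_identical(segF@mask, seg@mask)
  expect_error(segmentHighUptake(onehot, "fraction_of_max", 1.5), "(0, 1)")
})

test_that("raising the threshold shrinks the mask monotonically", {
  set.seed(18)
  pet <- Image2D(matrix(runif(256), 16, 16))
  prev <- NULL
  for (v in c(0.2, 0.4, 0.6, 0.8)) {
    m <- segmentHighUptake(pet, "fraction_of_max", v)@mask
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("the segmented phantom lesion contains the lesion core", {
  ph <- generatePhantom(4, size = 96)
  seg <- segmentHighUptake(ph@pet, "fraction_of_max", 0.4)
  core <- ph@lesionMask == 1 &
    pixels(ph@pet) >= 0.8 * max(pixels(ph@pet))
  expect_gt(sum(core), 0)
  expect_true(all(seg@mask[core] == 1))
  expect_gt(accuracyMetrics(seg, ph@lesionMask)[["dice"]], 0.5)
})

test_that("agreement metrics match closed forms", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(unname(accuracyMetrics(a, a)), c(1, 1, 1))

  b <- matrix(c(0, 0, 1, 1), 2, 2)
  m <- accuracyMetrics(a, b)
  expect_equal(unname(m), c(0, 0, 0))

  # prediction covers truth plus an equal-size extra area: dice 2/3
  truth <- matrix(0, 4, 4); truth[1:2, 1] <- 1
  pred <- truth; pred[1:2, 2] <- 1
  m2 <- accuracyMetrics(pred, truth)
  expect_equal(m2[["dice"]], 2 / 3)
  expect_equal(m2[["jaccard"]], 1 / 2)
  expect_equal(m2[["pixel_accuracy"]], 14 / 16)

  # both empty: defined as perfect agreement
  z <- matrix(0, 3, 3)
  expect_equal(unname(accuracyMetrics(z, z)), c(1, 1, 1))
  expect_error(accuracyMetrics(a, matrix(0, 3, 3)), "dimensions")
})

test_that("jaccard never exceeds dice on random mask pairs", {
  set.seed(28)
  for (rep in 1:25) {
    a <- matrix(rbinom(100, 1, 0.3), 10, 10)
    b <- matrix(rbinom(100, 1, 0.5), 10, 10)
    m <- accuracyMetrics(a, b)
    expect_lte(m[["dice"]], 1)
    expect_lte(m[["jaccard"]], m[["dice"]] + 1e-12)
  }
})

test_that("relative error normalizes by the stated component scales", {
  expect_equal(relativeError(c(0.1, 4, -3), c(0.1, 4, -3), c(0.3, 10, 10)),
               0)
  # off by a full scale on one of three components
  expect_equal(relativeError(c(1, 0, 0), c(0, 0, 0), 1), 100 / 3,
               tolerance = 1e-9)
  expect_error(relativeError(1:3, 1:3, 0), "positive")
  expect_error(relativeError(1:3, 1:2, 1), "length")
})
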