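test_that("mapPoint follows the printed rotation-plus-translation form", {
  expect_equal(mapPoint(rigidTransform(0, 0, 0), c(3, 4)), c(3, 4))
  # quarter turn about the origin: (1, 0) -> (0, 1)
  expect_equal(mapPoint(rigidTransform(pi / 2), c(1, 0)), c(0, 1),
               tolerance = 1e-12)
  # translation components act on row then column
  expect_equal(mapPoint(rigidTransform(0, 2, -3), c(1, 1)), c(3, -2))
})

test_that("compose and invert satisfy the rigid-group laws", {
  id <- rigidTransform()
  T1 <- rigidTransform(0.3, 4, -2)
  expect_equal(transformParams(composeTransforms(T1, id)),
               transformParams(T1))
  expect_equal(transformParams(invertTransform(id)), transformParams(id))
  rt <- composeTransforms(T1, invertTransform(T1))
  expect_true(all(abs(transformParams(rt)) < 1e-9))

  set.seed(5)
  for (rep in 1:10) {
    T2 <- rigidTransform(runif(1, -pi, pi), runif(1, -9, 9), runif(1, -9, 9))
    p <- runif(2, -20, 20)
    expect_equal(mapPoint(composeTransforms(T1, T2), p),
                 mapPoint(T1, mapPoint(T2, p)), tolerance = 1e-9)
    expect_equal(mapPoint(invertTransform(T2), mapPoint(T2, p)), p,
                 tolerance = 1e-9)
  }
})

test_that("rotation preserves pairwise distances", {
  set.seed(15)
  T <- rigidTransform(0.77, 3, -5)
  pts <- matrix(runif(20, -15, 15), ncol = 2)
  mapped <- mapPoint(T, pts)
  expect_equal(as.vector(dist(mapped)), as.vector(dist(pts)),
               tolerance = 1e-9)
})

test_that("identity resampling is exact with full overlap", {
  set.seed(25)
  img <- Image2D(matrix(runif(96), 12, 8))
  for (interp in c("nearest", "bilinear")) {
    out <- resampleImage(img, rigidTransform(), interp)
    expect_equal(pixels(out$image), pixels(img))
    expect_true(all(out$overlap))
  }
})

test_that("integer translation shifts pixels and trims the overlap", {
  img <- Image2D(matrix(1:64, 8, 8))
  out <- resampleImage(img, rigidTransform(0, 0, 3), "nearest", fill = -1)
  # index-shift oracle: out[, j] = img[, j-3]
  expect_equal(pixels(out$image)[, 4:8], pixels(img)[, 1:5])
  expect_identical(unname(colSums(!out$overlap)), c(8, 8, 8, rep(0, 5)))
  expect_true(all(pixels(out$image)[, 1:3] == -1))
})

test_that("half-turn of a point-symmetric image is invariant", {
  set.seed(35)
  m <- matrix(runif(144), 12, 12)
  sym <- (m + m[12:1, 12:1]) / 2
  out <- resampleImage(Image2D(sym), rigidTransform(pi), "bilinear")
  expect_equal(pixels(out$image), sym, tolerance = 1e-6)
})

test_that("warping forward then back restores the double-overlap region", {
  img <- Image2D(matrix(runif(100), 10, 10))
  T <- rigidTransform(0, 2, -3)
  fwd <- resampleImage(img, T, "nearest")
  back <- resampleImage(fwd$image, invertTransform(T), "nearest")
  both <- back$overlap &
    resampleImage(Image2D(1 * fwd$overlap), invertTransform(T),
                  "nearest")$image@pixels > 0.5
  expect_gt(sum(both), 0)
  expect_equal(pixels(back$image)[both], pixels(img)[both])
})

test_that("transforms serialize to one plain-text line and back", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  T <- rigidTransform(-0.123456789, 4.25, -7.5)
  writeTransform(T, tmp)
  expect_identical(length(readLines(tmp)), 1L)
  expect_equal(transformParams(readTransform(tmp)), transformParams(T))
})

test_that("unknown interpolation modes are rejected", {
  img <- Image2D(matrix(0, 8, 8))
  expect_error(resampleImage(img, rigidTransform(), "cubic"))
})
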