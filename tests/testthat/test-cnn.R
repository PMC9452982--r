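test_that("input normalization maps endpoints, midpoint and constants", {
  img <- Image2D(matrix(c(0, 255, 127.5, 10), 2, 2))
  u <- normalizeToCNNRange(img)
  expect_equal(u[1, 1], -1)
  expect_equal(u[2, 1], 1)
  expect_equal(u[1, 2], 0)
  expect_true(all(normalizeToCNNRange(Image2D(matrix(5, 4, 4))) == -1))
})

test_that("zero templates give pure exponential decay of the state", {
  z0 <- cnnTemplates(matrix(0, 3, 3), matrix(0, 3, 3), 0)
  x0 <- matrix(runif(64, -0.9, 0.9), 8, 8)
  prev <- abs(x0)
  for (d in c(2, 4, 8)) {
    st <- cnnEvolve(matrix(0, 8, 8), z0, step = 0.1, duration = d,
                    initialState = x0)
    expect_true(all(abs(st@x) <= prev + 1e-12))
    prev <- abs(st@x)
  }
  expect_true(all(abs(prev) < 0.01))
})

test_that("centre-only feedback matches the scalar Euler oracle cellwise", {
  # A with a00 = 2, B = 0, z = 0, uniform state: every cell follows the
  # scalar recursion x <- x + h(-x + 2 y(x)); interior and boundary alike
  tmpl <- cnnTemplates(matrix(c(0, 0, 0, 0, 2, 0, 0, 0, 0), 3, 3),
                       matrix(0, 3, 3), 0)
  h <- 0.1; d <- 5
  xs <- 0.5
  for (k in seq_len(round(d / h)))
    xs <- xs + h * (-xs + 2 * (0.5 * (abs(xs + 1) - abs(xs - 1))))
  st <- cnnEvolve(matrix(0, 6, 6), tmpl, step = h, duration = d,
                  initialState = matrix(0.5, 6, 6))
  expect_equal(st@x, matrix(xs, 6, 6), tolerance = 1e-12)
  expect_true(all(st@y == 1))  # saturates to +1
})

test_that("outputs obey the piecewise-linear law and stay within [-1, 1]", {
  set.seed(31)
  tmpl <- cnnTemplates(matrix(runif(9, -1, 1), 3, 3),
                       matrix(runif(9, -1, 1), 3, 3), 0.3)
  st <- cnnEvolve(matrix(runif(49, -1, 1), 7, 7), tmpl,
                  step = 0.05, duration = 3)
  expect_true(all(abs(st@y) <= 1))
  lin <- abs(st@x) <= 1
  expect_equal(st@y[lin], st@x[lin])
  expect_equal(st@y[!lin], sign(st@x[!lin]))
})

test_that("constant CT yields an empty edge image", {
  e <- edgeExtract(Image2D(matrix(42, 16, 16)))
  expect_true(all(pixels(e) == 0))
  expect_identical(modality(e), "EDGE")
})

test_that("half-plane step is detected only along the transition", {
  ct <- Image2D(cbind(matrix(0, 16, 8), matrix(255, 16, 8)))
  e <- pixels(edgeExtract(ct))
  hit <- which(e == 1, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  # support confined to the two columns adjacent to the boundary
  expect_true(all(hit[, "col"] %in% c(8, 9)))
  # and a subset of the brute-force local-transition oracle
  u <- matrix(-1, 16, 16); u[, 9:16] <- 1
  expect_true(all(oppositeNeighbourMask(u)[e == 1]))
})

test_that("a single bright pixel is flagged within its neighbourhood", {
  ct <- Image2D(matrix(0, 12, 12))
  px <- pixels(ct); px[6, 7] <- 200
  ct <- Image2D(px)
  e <- pixels(edgeExtract(ct))
  expect_equal(e[6, 7], 1)
  u <- matrix(-1, 12, 12); u[6, 7] <- 1
  expect_true(all(oppositeNeighbourMask(u)[e == 1]))
})

test_that("edge pixels always have an opposite-valued 8-neighbour", {
  set.seed(41)
  for (rep in 1:8) {
    u <- randomBinaryImage(20)
    e <- pixels(edgeExtract(Image2D(u)))
    if (length(unique(as.vector(u))) == 1) {
      expect_true(all(e == 0))
    } else {
      expect_true(all(oppositeNeighbourMask(u)[e == 1]))
    }
  }
})

test_that("templates round-trip through the plain-text config format", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# edge template", "0 0 0", "0 1 0", "0 0 0",
               "-1 -1 -1", "-1 8 -1", "-1 -1 -1", "-1"), tmp)
  tl <- readTemplates(tmp)
  ref <- edgeTemplates()
  expect_equal(tl@A, ref@A)
  expect_equal(tl@B, ref@B)
  expect_equal(tl@z, ref@z)
})

test_that("bad integration or template parameters are rejected", {
  expect_error(cnnEvolve(matrix(0, 4, 4), edgeTemplates(), step = 0),
               "positive")
  expect_error(cnnEvolve(matrix(0, 4, 4), edgeTemplates(), step = 1,
                         duration = 0.5), "duration")
  expect_error(cnnTemplates(matrix(NA_real_, 3, 3), matrix(0, 3, 3), 0),
               "finite")
})
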