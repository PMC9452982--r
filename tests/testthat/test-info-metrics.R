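test_that("joint histogram counts co-located pairs and normalizes", {
  # hand enumeration: labels [[0,0],[1,1]] against itself
  q <- makeQ(rbind(c(0, 0), c(1, 1)), 2)
  h <- jointHistogram(q, q)
  expect_identical(pairCounts(h), matrix(c(2L, 0L, 0L, 2L), 2, 2))
  expect_identical(nPairs(h), 4L)
  expect_equal(diag(jointProb(h)), c(0.5, 0.5))

  # single-cell case
  h0 <- jointHistogram(makeQ(matrix(0, 3, 3), 2), makeQ(matrix(0, 3, 3), 3))
  expect_identical(pairCounts(h0)[1, 1], 9L)
  expect_equal(jointProb(h0)[1, 1], 1)

  # normalization and marginal consistency on random inputs
  set.seed(7)
  for (rep in 1:10) {
    hu <- makeQ(matrix(sample(0:3, 30, TRUE), 5, 6), 4)
    hd <- makeQ(matrix(sample(0:4, 30, TRUE), 5, 6), 5)
    h <- jointHistogram(hu, hd)
    expect_equal(sum(jointProb(h)), 1, tolerance = 1e-12)
    expect_equal(marginalU(h), rowSums(jointProb(h)), tolerance = 1e-12)
    expect_equal(marginalD(h), colSums(jointProb(h)), tolerance = 1e-12)
  }
})

test_that("mask restricts the counted pixels and cannot be empty", {
  qU <- makeQ(rbind(c(0, 1), c(1, 0)), 2)
  # the diagonal pixels both carry label 0 in qU
  h <- jointHistogram(qU, qU, mask = rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  expect_identical(nPairs(h), 2L)
  expect_identical(pairCounts(h), matrix(c(2L, 0L, 0L, 0L), 2, 2))
  expect_error(jointHistogram(qU, qU, matrix(FALSE, 2, 2)), "mask")
  expect_error(jointHistogram(qU, makeQ(matrix(0L, 3, 3), 2)), "dimension")
})

test_that("entropy matches closed forms with the 0 log 0 convention", {
  expect_equal(shannonEntropy(1), 0)
  expect_equal(shannonEntropy(c(0.5, 0.5)), 1)
  expect_equal(shannonEntropy(rep(0.25, 4)), 2)
  expect_equal(shannonEntropy(c(0.5, 0.5, 0, 0)), 1)  # zero cells ignored
  expect_error(shannonEntropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannonEntropy(c(0.3, 0.3)), "sum")
})

test_that("mutual information reproduces hand-computed cases", {
  # identical images: I(U,U) = H(U) = 1 bit for occupancies (2, 2)
  q <- makeQ(rbind(c(0, 0), c(1, 1)), 2)
  mi <- mutualInformation(jointHistogram(q, q))
  expect_equal(mi@I, 1)
  expect_equal(mi@I, mi@HU)

  # independent pattern: joint uniform over 4 cells, I = 0
  qU <- makeQ(rbind(c(0, 0), c(1, 1)), 2)
  qD <- makeQ(rbind(c(0, 1), c(0, 1)), 2)
  mi2 <- mutualInformation(jointHistogram(qU, qD))
  expect_equal(mi2@I, 0)
  expect_equal(mi2@HUD, 2)
})

test_that("direct MI and entropy-identity MI agree on random histograms", {
  set.seed(17)
  for (rep in 1:50) {
    mi <- mutualInformation(randomHistogram(sample(2:6, 1), sample(2:6, 1)))
    expect_lt(abs(mi@I - (mi@HU + mi@HD - mi@HUD)), 1e-9)
    expect_gte(mi@I, -1e-12)
    expect_lte(mi@I, min(mi@HU, mi@HD) + 1e-9)
    expect_lte(mi@HUD, mi@HU + mi@HD + 1e-12)
  }
})

test_that("MI is symmetric under transposing the histogram", {
  set.seed(27)
  for (rep in 1:20) {
    h <- randomHistogram(4, 6)
    ht <- new("JointHistogram", counts = t(pairCounts(h)),
              levels = rev(h@levels))
    expect_lt(abs(mutualInformation(h)@I - mutualInformation(ht)@I), 1e-12)
  }
})

test_that("merging two gray levels never increases MI", {
  set.seed(37)
  for (rep in 1:20) {
    h <- randomHistogram(5, 4)
    counts <- pairCounts(h)
    merged <- rbind(counts[1, ] + counts[2, ], counts[-(1:2), ])
    hm <- new("JointHistogram", counts = merged,
              levels = c(nrow(merged), ncol(merged)))
    expect_lte(mutualInformation(hm)@I, mutualInformation(h)@I + 1e-12)
  }
})
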