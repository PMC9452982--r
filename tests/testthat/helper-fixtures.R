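# small fixture builders shared across test files

# QuantizedImage straight from a label matrix
makeQ <- function(labels, levels) {
  storage.mode(labels) <- "integer"
  new("QuantizedImage", labels = labels, levels = as.integer(levels),
      sourceRange = c(0, levels - 1))
}

# random joint histogram with occasional zero cells
randomHistogram <- function(lu = 4, ld = 5) {
  counts <- matrix(rpois(lu * ld, 3), lu, ld)
  counts[sample(lu * ld, lu)] <- 0
  if (sum(counts) == 0) counts[1, 1] <- 1
  new("JointHistogram", counts = counts, levels = as.integer(c(lu, ld)))
}

# random binary image in {-1, +1} with blocky structure
randomBinaryImage <- function(n = 24) {
  base <- matrix(sample(c(-1, 1), ceiling(n / 4)^2, replace = TRUE),
                 ceiling(n / 4))
  big <- base[rep(seq_len(nrow(base)), each = 4),
              rep(seq_len(ncol(base)), each = 4)]
  big[seq_len(n), seq_len(n)]
}

# brute-force oracle: pixels with at least one 8-neighbour of opposite
# binary value
oppositeNeighbourMask <- function(u) {
  n <- nrow(u); m <- ncol(u)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n || jj < 1 || jj > m) next
      if (u[ii, jj] != u[i, j]) out[i, j] <- TRUE
    }
  }
  out
}

# reduced search grid for fast registration tests (identity included)
smallConfig <- function(mode = "ct_raw")
  registrationConfig(referenceMode = mode, betaRange = c(-0.1, 0.1),
                     betaStep = 0.05, tRange = c(-4, 4), tStep = 2)
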