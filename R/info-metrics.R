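#' Joint histogram of two quantized images
#'
#' Counts co-located gray-level pairs: \code{counts[u+1, d+1]} is the
#' number of pixel positions where the floating image has level u and
#' the reference has level d. Dividing by the total count N gives the
#' joint probability estimate j_UD(u, d) = n_ud / N, whose row/column
#' sums are the marginals j_U and j_D. An optional mask restricts the
#' count to selected pixels (used to confine MI to the overlap region of
#' a resampled image, so that fill values never enter the histogram).
#'
#' @param qU,qD [QuantizedImage-class] objects of identical shape
#'   (floating and reference).
#' @param mask optional logical matrix of the same shape; only TRUE
#'   pixels are counted.
#' @return a [JointHistogram-class].
#' @examples
#' q <- function(m) new("QuantizedImage", labels = m, levels = 2L,
#'                      sourceRange = c(0, 1))
#' h <- jointHistogram(q(rbind(0:1, 0:1)), q(rbind(0:1, 0:1)))
#' pairCounts(h)
#' @export
jointHistogram <- function(qU, qD, mask = NULL) {
  stopifnot(is(qU, "QuantizedImage"), is(qD, "QuantizedImage"))
  if (!identical(dim(qU@labels), dim(qD@labels)))
    stop("images must have identical dimensions")
  lu <- qU@labels; ld <- qD@labels
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(lu)))
      stop("mask must match image dimensions")
    if (!any(mask))
      stop("mask selects no pixels (degenerate input)")
    lu <- lu[mask]; ld <- ld[mask]
  }
  jointHistogramFromLabels(lu, ld, qU@levels, qD@levels)
}

# core counting path, shared with the registration inner loop
jointHistogramFromLabels <- function(lu, ld, LU, LD) {
  counts <- matrix(tabulate(as.integer(lu) * LD + as.integer(ld) + 1L,
                            nbins = LU * LD),
                   nrow = LU, ncol = LD, byrow = TRUE)
  new("JointHistogram", counts = counts, levels = c(LU, LD))
}

#' @rdname JointHistogram-class
#' @export
setMethod("pairCounts", "JointHistogram", function(object) object@counts)

#' @rdname JointHistogram-class
#' @export
setMethod("nPairs", "JointHistogram", function(object) sum(object@counts))

#' @rdname JointHistogram-class
#' @export
setMethod("jointProb", "JointHistogram",
          function(object) object@counts / sum(object@counts))

#' @rdname JointHistogram-class
#' @export
setMethod("marginalU", "JointHistogram",
          function(object) rowSums(object@counts) / sum(object@counts))

#' @rdname JointHistogram-class
#' @export
setMethod("marginalD", "JointHistogram",
          function(object) colSums(object@counts) / sum(object@counts))

setMethod("show", "JointHistogram", function(object) {
  cat(sprintf("JointHistogram %d x %d levels, N = %d pairs\n",
              object@levels[1], object@levels[2], sum(object@counts)))
})

#' Shannon entropy of a probability vector
#'
#' \eqn{-\sum_i p_i \log_2 p_i} in bits, with the convention
#' \eqn{0 \log 0 = 0} (zero cells contribute nothing, as required for
#' sparse histograms).
#'
#' @param p numeric vector (or matrix, flattened) of probabilities
#'   summing to 1 within 1e-9.
#' @return entropy in bits.
#' @examples
#' shannonEntropy(c(0.5, 0.5))      # 1 bit
#' shannonEntropy(rep(0.25, 4))     # 2 bits
#' @export
shannonEntropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint histogram
#'
#' Computes I(U, D) directly from the joint and marginal probabilities,
#' \deqn{I(U,D) = \sum_{u,d} j_{UD}(u,d) \log_2
#'       \frac{j_{UD}(u,d)}{j_U(u)\, j_D(d)},}
#' skipping zero-probability cells, together with the marginal and joint
#' entropies. The entropy identity I = H(U) + H(D) - H(U,D) holds to
#' numerical precision and is exposed through the returned object.
#'
#' @param h a [JointHistogram-class].
#' @return an [MIResult-class] with slots \code{HU}, \code{HD},
#'   \code{HUD} and \code{I}, all in bits.
#' @examples
#' q <- function(m) new("QuantizedImage", labels = m, levels = 2L,
#'                      sourceRange = c(0, 1))
#' mutualInformation(jointHistogram(q(rbind(0:1, 0:1)),
#'                                  q(rbind(0:1, 0:1))))
#' @export
mutualInformation <- function(h) {
  stopifnot(is(h, "JointHistogram"))
  j <- jointProb(h)
  ju <- rowSums(j); jd <- colSums(j)
  nz <- which(j > 0, arr.ind = TRUE)
  jv <- j[nz]
  I <- sum(jv * log2(jv / (ju[nz[, 1]] * jd[nz[, 2]])))
  new("MIResult",
      HU = shannonEntropy(ju), HD = shannonEntropy(jd),
      HUD = shannonEntropy(j), I = I)
}

setMethod("show", "MIResult", function(object) {
  cat(sprintf("MIResult: H(U) = %.6g, H(D) = %.6g, H(U,D) = %.6g, I = %.6g bits\n",
              object@HU, object@HD, object@HUD, object@I))
})

# fast scalar MI from a counts matrix (registration inner loop)
miFromCounts <- function(counts) {
  N <- sum(counts)
  j <- counts / N
  ju <- rowSums(j); jd <- colSums(j)
  nz <- which(j > 0, arr.ind = TRUE)
  jv <- j[nz]
  sum(jv * log2(jv / (ju[nz[, 1]] * jd[nz[, 2]])))
}
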