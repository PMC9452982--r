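#' Fuse a registered PET with the CT as a colour overlay
#'
#' The CT is rendered as a min-max-normalized grayscale base layer; the
#' PET is passed through a "hot" colormap (black - red - yellow - white)
#' and alpha-blended on top: \code{out = (1 - alpha) * ctGray +
#' alpha * hot(petNorm)}, channelwise, clamped to \code{[0, 1]}. With
#' \code{alpha = 0} the output luminance equals the normalized CT; with
#' \code{alpha = 1} over a zero CT it equals the colormapped PET.
#'
#' @param petReg registered PET [Image2D-class].
#' @param ct CT [Image2D-class], same shape.
#' @param alpha PET opacity in \code{[0, 1]}.
#' @return numeric H x W x 3 array (RGB in \code{[0, 1]}).
#' @export
fuseOverlay <- function(petReg, ct, alpha = 0.5) {
  stopifnot(is(petReg, "Image2D"), is(ct, "Image2D"))
  if (!identical(dim(petReg), dim(ct)))
    stop("PET and CT must have identical dimensions")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  normalize01 <- function(px) {
    rg <- range(px)
    if (diff(rg) > 0) (px - rg[1]) / diff(rg) else px * 0
  }
  ctG <- normalize01(ct@pixels)
  petN <- normalize01(petReg@pixels)
  hot <- hotColormap(petN)
  out <- array(0, c(dim(ctG), 3L))
  for (ch in 1:3)
    out[, , ch] <- pmin(pmax((1 - alpha) * ctG + alpha * hot[, , ch], 0), 1)
  out
}

# "hot" colormap: ramps red on [0,1/3], green on [1/3,2/3], blue on [2/3,1]
hotColormap <- function(v) {
  out <- array(0, c(dim(v), 3L))
  out[, , 1] <- pmin(3 * v, 1)
  out[, , 2] <- pmin(pmax(3 * v - 1, 0), 1)
  out[, , 3] <- pmin(pmax(3 * v - 2, 0), 1)
  out
}

#' Segment the high-uptake (high-metabolism) region of a PET image
#'
#' Thresholds the registered PET: with \code{method = "fraction_of_max"}
#' the mask keeps pixels with intensity >= \code{value * max(pet)}
#' (\code{value} in (0, 1)); with \code{method = "fixed"} it keeps
#' pixels >= \code{value}. Higher thresholds give nested (subset)
#' masks.
#'
#' @param petReg registered PET [Image2D-class].
#' @param method \code{"fraction_of_max"} or \code{"fixed"}.
#' @param value threshold fraction or absolute intensity.
#' @return a [SegmentationResult-class].
#' @examples
#' pet <- Image2D(matrix(c(100, rep(0, 63)), 8, 8))
#' segmentHighUptake(pet, "fraction_of_max", 0.5)@nForeground
#' @export
segmentHighUptake <- function(petReg,
                              method = c("fraction_of_max", "fixed"),
                              value = 0.4) {
  stopifnot(is(petReg, "Image2D"))
  method <- match.arg(method)
  if (method == "fraction_of_max") {
    if (value <= 0 || value >= 1)
      stop("'value' must be in (0, 1) for fraction_of_max")
    thr <- value * max(petReg@pixels)
  } else {
    if (!is.finite(value)) stop("'value' must be finite")
    thr <- value
  }
  mask <- (petReg@pixels >= thr) * 1
  new("SegmentationResult", mask = mask, thresholdUsed = thr,
      nForeground = as.integer(sum(mask)))
}

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d foreground pixels (threshold %.5g)\n",
              object@nForeground, object@thresholdUsed))
})

#' Segmentation agreement metrics
#'
#' Pixel accuracy (fraction of agreeing pixels), Dice coefficient
#' \eqn{2|A \cap B| / (|A| + |B|)} and Jaccard index
#' \eqn{|A \cap B| / |A \cup B|} between a predicted and a true binary
#' mask. When both masks are empty, Dice and Jaccard are defined as 1
#' (perfect agreement on "nothing to segment").
#'
#' @param mask predicted binary matrix (or [SegmentationResult-class]).
#' @param truth true binary matrix, same shape.
#' @return named numeric: \code{pixel_accuracy}, \code{dice},
#'   \code{jaccard}.
#' @export
accuracyMetrics <- function(mask, truth) {
  if (is(mask, "SegmentationResult")) mask <- mask@mask
  mask <- as.matrix(mask); truth <- as.matrix(truth)
  if (!identical(dim(mask), dim(truth)))
    stop("mask and truth must have identical dimensions")
  a <- mask > 0; b <- truth > 0
  inter <- sum(a & b); union <- sum(a | b)
  c(pixel_accuracy = mean(a == b),
    dice = if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b)),
    jaccard = if (union == 0) 1 else inter / union)
}

#' Normalized relative error between parameter vectors
#'
#' Mean over components of \code{|estimate - truth| / scale * 100}. For
#' scoring transform recovery the natural scales are the search-range
#' half-widths (0.3 rad for the rotation, 10 px for each translation
#' with the default [registrationConfig()]), so each parameter's error
#' is expressed as a percentage of the motion range the optimizer had
#' to resolve; the normalization is reported alongside the score
#' wherever the package prints it.
#'
#' @param estimate,truth numeric vectors of equal length.
#' @param scale positive numeric vector (recycled) of per-component
#'   scales.
#' @return mean relative error in percent.
#' @examples
#' relativeError(c(0.1, 4, -3), c(0.1, 4, -3), c(0.3, 10, 10))  # 0
#' @export
relativeError <- function(estimate, truth, scale) {
  estimate <- as.numeric(estimate); truth <- as.numeric(truth)
  if (length(estimate) != length(truth))
    stop("'estimate' and 'truth' must have equal length")
  scale <- rep_len(as.numeric(scale), length(truth))
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("'scale' must be positive and finite")
  mean(abs(estimate - truth) / scale) * 100
}
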