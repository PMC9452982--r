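#' Construct a rigid 2D transform
#'
#' Rotation by \code{beta} radians about the image centre followed by a
#' translation of \code{tx} pixels along the first (row) axis and
#' \code{ty} pixels along the second (column) axis. In centred
#' coordinates v, the map is \eqn{v' = R(\beta) v + t} with the standard
#' rotation matrix \eqn{R(\beta) = [[\cos\beta, -\sin\beta],
#' [\sin\beta, \cos\beta]]}.
#'
#' @param beta rotation angle, radians.
#' @param tx,ty translations, pixels (row axis, column axis).
#' @return a [RigidTransform2D-class].
#' @export
rigidTransform <- function(beta = 0, tx = 0, ty = 0) {
  new("RigidTransform2D", beta = as.numeric(beta), tx = as.numeric(tx),
      ty = as.numeric(ty))
}

#' @rdname RigidTransform2D-class
#' @export
setMethod("transformParams", "RigidTransform2D", function(object)
  c(beta = object@beta, tx = object@tx, ty = object@ty))

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: beta = %.6g rad, t = (%.6g, %.6g) px\n",
              object@beta, object@tx, object@ty))
})

# image-centre origin of an nr x nc grid, in 0-based pixel-centre coords
gridCenter <- function(nr, nc) c((nr - 1) / 2, (nc - 1) / 2)

#' Map a point through a rigid transform
#'
#' @param T a [RigidTransform2D-class].
#' @param p numeric(2) point (row, col) or a 2-column matrix of points,
#'   in 0-based pixel-centre coordinates.
#' @param center rotation centre (row, col); defaults to the origin, so
#'   callers working in image coordinates should pass the image centre.
#' @return transformed point(s), same shape as \code{p}.
#' @examples
#' mapPoint(rigidTransform(pi / 2), c(1, 0))   # quarter turn: (0, 1)
#' @export
mapPoint <- function(T, p, center = c(0, 0)) {
  stopifnot(is(T, "RigidTransform2D"))
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  cb <- cos(T@beta); sb <- sin(T@beta)
  v1 <- pm[, 1] - center[1]
  v2 <- pm[, 2] - center[2]
  out <- cbind(cb * v1 - sb * v2 + center[1] + T@tx,
               sb * v1 + cb * v2 + center[2] + T@ty)
  if (is.matrix(p)) out else drop(out)
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(T1, T2)} returns the transform mapping p to
#' T1(T2(p)); \code{invertTransform(T)} returns the transform undoing T,
#' so that \code{composeTransforms(T, invertTransform(T))} is the
#' identity to numerical precision.
#'
#' @param T1,T2,T [RigidTransform2D-class] objects.
#' @return a [RigidTransform2D-class].
#' @export
composeTransforms <- function(T1, T2) {
  cb <- cos(T1@beta); sb <- sin(T1@beta)
  rigidTransform(T1@beta + T2@beta,
                 cb * T2@tx - sb * T2@ty + T1@tx,
                 sb * T2@tx + cb * T2@ty + T1@ty)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(T) {
  cb <- cos(T@beta); sb <- sin(T@beta)
  rigidTransform(-T@beta,
                 -(cb * T@tx + sb * T@ty),
                 -(-sb * T@tx + cb * T@ty))
}

#' Serialize / deserialize a rigid transform
#'
#' Plain-text format: one line, "beta tx ty" (radians, pixels).
#'
#' @param T a [RigidTransform2D-class].
#' @param path text file path.
#' @return \code{readTransform} returns a [RigidTransform2D-class].
#' @export
writeTransform <- function(T, path) {
  writeLines(sprintf("%.17g %.17g %.17g", T@beta, T@tx, T@ty), path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  vals <- as.numeric(strsplit(trimws(readLines(path)[1]), "\\s+")[[1]])
  if (length(vals) != 3L || any(!is.finite(vals)))
    stop("transform file must hold three finite numbers: beta tx ty")
  rigidTransform(vals[1], vals[2], vals[3])
}

#' Resample an image through a rigid transform
#'
#' Backward (pull) warping: the output pixel at position q takes the
#' interpolated value of the input at \eqn{T^{-1}(q)}, with rotation
#' about the image centre. Output pixels whose back-mapped source falls
#' outside the input bounds take \code{fill} and are flagged FALSE in
#' the overlap mask, so downstream histogramming can exclude them (fill
#' intensities biasing MI is a known registration artifact).
#'
#' @param img an [Image2D-class].
#' @param T a [RigidTransform2D-class]; the transform applied to the
#'   image content.
#' @param interpolation \code{"bilinear"} (default) or \code{"nearest"}.
#' @param fill intensity for out-of-bounds output pixels.
#' @return list with elements \code{image} (the resampled
#'   [Image2D-class]) and \code{overlap} (logical matrix).
#' @examples
#' img <- Image2D(matrix(1:64, 8, 8))
#' out <- resampleImage(img, rigidTransform(0, 0, 3), "nearest")
#' sum(!out$overlap)   # 3 columns fall outside
#' @export
resampleImage <- function(img, T,
                          interpolation = c("bilinear", "nearest"),
                          fill = 0) {
  stopifnot(is(img, "Image2D"), is(T, "RigidTransform2D"))
  interpolation <- match.arg(interpolation)
  px <- img@pixels
  nr <- nrow(px); nc <- ncol(px)
  ctr <- gridCenter(nr, nc)
  Tinv <- invertTransform(T)
  # back-map every output pixel centre to its source position
  q1 <- rep(seq_len(nr) - 1, times = nc)
  q2 <- rep(seq_len(nc) - 1, each = nr)
  cb <- cos(Tinv@beta); sb <- sin(Tinv@beta)
  v1 <- q1 - ctr[1]; v2 <- q2 - ctr[2]
  s1 <- cb * v1 - sb * v2 + ctr[1] + Tinv@tx
  s2 <- sb * v1 + cb * v2 + ctr[2] + Tinv@ty
  out <- resampleCore(px, s1, s2, interpolation, fill)
  list(image = Image2D(matrix(out$values, nr, nc), spacing = img@spacing,
                       modality = img@modality),
       overlap = matrix(out$inside, nr, nc))
}

# Interpolate px at fractional 0-based source coords (s1, s2).
# A pixel's extent reaches half a pixel beyond its centre, so sources in
# [-0.5, n-0.5] are inside the image; interpolation coordinates are
# clamped to the centre grid in the half-pixel rim (edge replication).
# This keeps sub-half-pixel transforms at full overlap, so the masked-MI
# objective is not inflated by cropping border pixels from the histogram
# for near-identity candidates.
resampleCore <- function(px, s1, s2, interpolation, fill) {
  nr <- nrow(px); nc <- ncol(px)
  inside <- s1 >= -0.5 & s1 <= nr - 0.5 & s2 >= -0.5 & s2 <= nc - 0.5
  if (interpolation == "nearest") {
    vals <- rep(fill, length(s1))
    idx <- which(inside)
    r <- pmin(pmax(round(s1[idx]), 0), nr - 1)
    c <- pmin(pmax(round(s2[idx]), 0), nc - 1)
    vals[idx] <- px[cbind(r + 1, c + 1)]
  } else {
    vals <- rep(fill, length(s1))
    idx <- which(inside)
    sc1 <- pmin(pmax(s1[idx], 0), nr - 1)
    sc2 <- pmin(pmax(s2[idx], 0), nc - 1)
    r0 <- floor(pmin(sc1, nr - 2)); c0 <- floor(pmin(sc2, nc - 2))
    fr <- sc1 - r0; fc <- sc2 - c0
    v00 <- px[cbind(r0 + 1, c0 + 1)]
    v01 <- px[cbind(r0 + 1, c0 + 2)]
    v10 <- px[cbind(r0 + 2, c0 + 1)]
    v11 <- px[cbind(r0 + 2, c0 + 2)]
    vals[idx] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                 fr * ((1 - fc) * v10 + fc * v11)
  }
  list(values = vals, inside = inside)
}
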