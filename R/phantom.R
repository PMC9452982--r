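# Separable Gaussian blur with replicate boundary; kernel truncated at
# 3 sigma. Deterministic, no FFT, so the phantom generator is exactly
# reproducible across platforms.
gaussianBlur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(px); nc <- ncol(px)
  ridx <- pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)
  padded <- px[ridx, ]           # rows pass
  out <- matrix(0, nr, nc)
  for (o in seq_along(k)) out <- out + k[o] * padded[o:(o + nr - 1), ]
  padded <- out[, cidx]          # columns pass
  out <- matrix(0, nr, nc)
  for (o in seq_along(k)) out <- out + k[o] * padded[, o:(o + nc - 1)]
  out
}

#' Generate a co-registered synthetic CT/PET phantom pair
#'
#' Builds a CT-like slice (piecewise-constant soft-tissue ellipse with
#' sharp, high-intensity bone structures: an elliptical rib ring and a
#' spine disk) and a matching PET-like slice (smooth body uptake, cold
#' bone, Gaussian "hot" lesions at sampled interior positions, Gaussian
#' blur emulating PET's low spatial resolution, additive Gaussian
#' noise), then displaces the PET by the requested rigid transform. The
#' true transform and the lesion mask (pixels within one
#' full-width-half-maximum of each lesion centre, in the CT frame) are
#' returned as ground truth for registration and segmentation
#' benchmarks.
#'
#' All stochastic choices (lesion positions, then the noise field) are
#' drawn in a fixed documented order from one stream keyed by
#' \code{seed}, so regeneration with the same arguments is
#' bit-identical; the caller's RNG state is left untouched.
#'
#' @param seed integer RNG seed.
#' @param size image side, pixels (>= 64); images are size x size.
#' @param nLesions number of hot lesions (>= 1).
#' @param beta,tx,ty rigid displacement applied to the PET (radians,
#'   pixels).
#' @param noiseSd additive Gaussian noise SD, in units of the PET
#'   intensity scale (body uptake 0.2, lesion peak about 1).
#' @param petBlurSigma Gaussian blur SD in pixels applied to the PET.
#' @param lesionSigma Gaussian lesion SD in pixels.
#' @return a [Phantom-class].
#' @examples
#' ph <- generatePhantom(1, size = 64)
#' ph@trueTransform
#' sum(ph@lesionMask)
#' @export
generatePhantom <- function(seed, size = 128, nLesions = 1, beta = 0,
                            tx = 0, ty = 0, noiseSd = 0.05,
                            petBlurSigma = 2, lesionSigma = 4) {
  if (size < 64) stop("'size' must be >= 64")
  if (nLesions < 1) stop("'nLesions' must be >= 1")
  seed <- as.integer(seed)

  # private RNG stream: save and restore the caller's state
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
            assign(".Random.seed", oldSeed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  ctr <- (size - 1) / 2
  a <- 0.38 * size; b <- 0.32 * size        # body semi-axes (rows, cols)
  rr <- matrix(rep(0:(size - 1), size), size) - ctr
  cc <- t(rr)
  ell <- (rr / a)^2 + (cc / b)^2            # body ellipse coordinate
  body <- ell <= 1

  # CT: air 0, soft tissue 0.35, bone 1.0 (rib ring + spine), sharp edges
  ring <- ell >= 0.80^2 & ell <= 0.88^2
  spineR <- 0.05 * size
  spine <- (rr - 0.55 * a)^2 + cc^2 <= spineR^2
  ctPx <- matrix(0, size, size)
  ctPx[body] <- 0.35
  ctPx[ring | spine] <- 1.0

  # PET base: body uptake 0.2, cold bone 0.08, air 0
  petPx <- matrix(0, size, size)
  petPx[body] <- 0.20
  petPx[ring | spine] <- 0.08

  # lesions: uniform draws inside 0.6 of the body axes, rejecting bone
  # and near-duplicate placements (two draws per attempt, in order)
  fwhm <- 2 * sqrt(2 * log(2)) * lesionSigma
  centers <- matrix(0, 0, 2)
  for (i in seq_len(nLesions)) {
    placed <- FALSE
    for (try in 1:100) {
      cand <- c(runif(1, -0.6 * a, 0.6 * a), runif(1, -0.6 * b, 0.6 * b))
      if ((cand[1] / (0.6 * a))^2 + (cand[2] / (0.6 * b))^2 > 1) next
      if ((cand[1] - 0.55 * a)^2 + cand[2]^2 <= (spineR + 2)^2) next
      if (nrow(centers) &&
          any(sqrt(rowSums(sweep(centers, 2, cand)^2)) < 2 * fwhm)) next
      centers <- rbind(centers, cand)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place lesion ", i, " inside the body in 100 tries")
  }
  for (i in seq_len(nrow(centers)))
    petPx <- petPx + 0.8 * exp(-((rr - centers[i, 1])^2 +
                                 (cc - centers[i, 2])^2) /
                               (2 * lesionSigma^2))

  petPx <- gaussianBlur(petPx, petBlurSigma)
  if (noiseSd > 0)
    petPx <- petPx + matrix(rnorm(size * size, 0, noiseSd), size, size)

  trueT <- rigidTransform(beta, tx, ty)
  petAligned <- Image2D(petPx, modality = "PET")
  petMoved <- if (beta == 0 && tx == 0 && ty == 0) petAligned
              else resampleImage(petAligned, trueT, "bilinear", fill = 0)$image

  lesionMask <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(centers)))
    lesionMask <- lesionMask |
      ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= fwhm^2)

  new("Phantom", ct = Image2D(ctPx, modality = "CT"), pet = petMoved,
      trueTransform = trueT, lesionMask = lesionMask * 1, seed = seed)
}

setMethod("show", "Phantom", function(object) {
  d <- dim(object@ct)
  cat(sprintf("Phantom (seed %d): %d x %d, true transform (beta %.4g, tx %.4g, ty %.4g), %d lesion-mask pixels\n",
              object@seed, d[1], d[2], object@trueTransform@beta,
              object@trueTransform@tx, object@trueTransform@ty,
              sum(object@lesionMask)))
})

#' Draw a random rigid displacement for phantom experiments
#'
#' Uniform draws of the rotation and translations within symmetric
#' bounds, from a stream keyed by \code{seed}; the caller's RNG state is
#' left untouched. Used to displace phantom PET images by a known truth
#' in the registration benchmarks.
#'
#' @param seed integer RNG seed.
#' @param betaMax rotation bound, radians (draw is in
#'   \code{[-betaMax, betaMax]}).
#' @param tMax translation bound, pixels, per axis.
#' @return a [RigidTransform2D-class].
#' @export
randomRigidTransform <- function(seed, betaMax = 0.2, tMax = 8) {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
            assign(".Random.seed", oldSeed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  rigidTransform(runif(1, -betaMax, betaMax), runif(1, -tMax, tMax),
                 runif(1, -tMax, tMax))
}
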