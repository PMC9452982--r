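#' Registration search settings
#'
#' Defaults cover typical single-slice PET/CT misalignment: rotation
#' grid \code{[-0.3, 0.3]} rad in steps of 0.05, translation grids
#' \code{[-10, 10]} px in steps of 2, then coordinate-descent refinement
#' with successive step halving down to 0.005 rad and 0.25 px. The
#' floating PET is quantized to \code{levels} gray levels (default 64);
#' with \code{referenceMode = "ct_edge"} the reference is the binary CNN
#' edge image of the CT and is histogrammed with 2 levels.
#'
#' @param levels gray levels for the floating image histogram.
#' @param referenceMode \code{"ct_edge"} or \code{"ct_raw"}.
#' @param betaRange,betaStep rotation grid, radians.
#' @param tRange,tStep translation grid, pixels.
#' @param tolBeta,tolT refinement stopping tolerances.
#' @param seed integer, reserved for randomized strategies (the default
#'   search is fully deterministic).
#' @return a [RegistrationConfig-class].
#' @export
registrationConfig <- function(levels = 64, referenceMode = "ct_edge",
                               betaRange = c(-0.3, 0.3), betaStep = 0.05,
                               tRange = c(-10, 10), tStep = 2,
                               tolBeta = 0.005, tolT = 0.25, seed = 1L) {
  new("RegistrationConfig", levels = as.integer(levels),
      referenceMode = referenceMode, betaRange = as.numeric(betaRange),
      betaStep = as.numeric(betaStep), tRange = as.numeric(tRange),
      tStep = as.numeric(tStep), tolBeta = as.numeric(tolBeta),
      tolT = as.numeric(tolT), seed = as.integer(seed))
}

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: u* = (beta %.5g rad, tx %.5g, ty %.5g), MI %.5g bits, %d evaluations%s\n",
              object@uStar@beta, object@uStar@tx, object@uStar@ty,
              object@finalMI, object@nEvals,
              if (object@lowOverlap) " [low overlap]" else ""))
})

#' Register a floating PET image to a CT reference by maximizing MI
#'
#' Recovers the rigid transform u* that maximizes the mutual information
#' between the transformed floating image and the reference:
#' \deqn{u^* = \arg\max_T I(U(T), D).}
#' With the default \code{referenceMode = "ct_edge"} the reference D is
#' the binary CNN edge image of the CT (PET edges are too blurred to
#' extract, so only the CT side is edge-lifted); with \code{"ct_raw"}
#' the CT gray values are used directly. The search is an exhaustive
#' coarse grid over (beta, tx, ty) followed by coordinate-descent
#' refinement with step halving, both fully deterministic. MI is always
#' computed over the overlap mask only, with the floating image
#' re-quantized against its fixed global intensity range after each
#' candidate warp. Ties in MI are broken toward the smallest
#' (|beta|, |tx|, |ty|), lexicographically, so no-motion is preferred
#' when the data cannot distinguish candidates.
#'
#' @param pet floating [Image2D-class] (at least 8x8).
#' @param ct reference [Image2D-class], same dimensions.
#' @param config a [RegistrationConfig-class].
#' @return a [RegistrationResult-class]; \code{lowOverlap} is flagged
#'   when the optimum's overlap covers under 10 percent of the pixels.
#' @examples
#' ph <- generatePhantom(1, size = 64, tx = 3, ty = -2, beta = 0)
#' res <- registerImages(ph@pet, ph@ct,
#'                       registrationConfig(betaRange = c(0, 0),
#'                                          betaStep = 0.05))
#' res@uStar
#' @export
registerImages <- function(pet, ct, config = registrationConfig()) {
  stopifnot(is(pet, "Image2D"), is(ct, "Image2D"),
            is(config, "RegistrationConfig"))
  if (any(dim(pet) < 8L) || any(dim(ct) < 8L))
    stop("registration inputs must be at least 8x8")
  if (!identical(dim(pet), dim(ct)))
    stop("floating and reference images must have identical dimensions")

  if (config@referenceMode == "ct_edge") {
    ref <- edgeExtract(ct)
    refLevels <- 2L
    refLabels <- quantizeValues(ref@pixels, refLevels, c(0, 1))
  } else {
    refLevels <- config@levels
    refLabels <- quantizeValues(ct@pixels, refLevels, range(ct@pixels))
  }

  px <- pet@pixels
  nr <- nrow(px); nc <- ncol(px)
  ctr <- gridCenter(nr, nc)
  petRange <- range(px)
  petLevels <- config@levels
  # output-pixel centres, reused for every candidate transform
  q1 <- rep(seq_len(nr) - 1, times = nc)
  q2 <- rep(seq_len(nc) - 1, each = nr)
  v1 <- q1 - ctr[1]; v2 <- q2 - ctr[2]

  evalMI <- function(beta, tx, ty) {
    # back-map through the inverse of (beta, tx, ty)
    tI <- invertTransform(rigidTransform(beta, tx, ty))
    cb <- cos(tI@beta); sb <- sin(tI@beta)
    s1 <- cb * v1 - sb * v2 + ctr[1] + tI@tx
    s2 <- sb * v1 + cb * v2 + ctr[2] + tI@ty
    rs <- resampleCore(px, s1, s2, "bilinear", fill = petRange[1])
    idx <- which(rs$inside)
    warpedLabels <- quantizeValues(
      matrix(rs$values[idx], ncol = 1), petLevels, petRange)
    counts <- jointHistogramFromLabels(warpedLabels, refLabels[idx],
                                       petLevels, refLevels)@counts
    list(mi = miFromCounts(counts), overlap = length(idx) / (nr * nc))
  }

  betterThan <- function(miA, pA, miB, pB) {
    # strict MI improvement, or equal MI and lexicographically smaller
    # (|beta|, |tx|, |ty|)
    if (miA > miB + 1e-12) return(TRUE)
    if (miA < miB - 1e-12) return(FALSE)
    kA <- abs(pA); kB <- abs(pB)
    for (i in 1:3) {
      if (kA[i] < kB[i] - 1e-12) return(TRUE)
      if (kA[i] > kB[i] + 1e-12) return(FALSE)
    }
    FALSE
  }

  betas <- seq(config@betaRange[1], config@betaRange[2],
               by = config@betaStep)
  ts <- seq(config@tRange[1], config@tRange[2], by = config@tStep)
  # snap accumulated rounding so a symmetric grid contains exact zero
  betas[abs(betas) < 1e-12] <- 0
  ts[abs(ts) < 1e-12] <- 0
  if (!length(betas) || !length(ts))
    stop("empty search grid")

  trace <- vector("list", length(betas) * length(ts)^2 + 512L)
  nev <- 0L
  best <- NULL; bestMI <- -Inf; bestOverlap <- 0
  record <- function(p, mi) {
    nev <<- nev + 1L
    if (nev > length(trace)) length(trace) <<- 2L * nev  # grow
    trace[[nev]] <<- c(p, mi)
  }
  consider <- function(p) {
    ev <- evalMI(p[1], p[2], p[3])
    record(p, ev$mi)
    if (is.null(best) || betterThan(ev$mi, p, bestMI, best)) {
      best <<- p; bestMI <<- ev$mi; bestOverlap <<- ev$overlap
    }
  }

  for (b in betas) for (t1 in ts) for (t2 in ts)
    consider(c(b, t1, t2))

  # coordinate descent with step halving down to the tolerances
  stepB <- config@betaStep / 2
  stepT <- config@tStep / 2
  while (stepB >= config@tolBeta || stepT >= config@tolT) {
    repeat {
      moved <- FALSE
      for (k in 1:3) {
        st <- if (k == 1) stepB else stepT
        if (k == 1 && stepB < config@tolBeta) next
        if (k > 1 && stepT < config@tolT) next
        for (sgn in c(-1, 1)) {
          cand <- best
          cand[k] <- cand[k] + sgn * st
          ev <- evalMI(cand[1], cand[2], cand[3])
          record(cand, ev$mi)
          if (betterThan(ev$mi, cand, bestMI, best)) {
            best <- cand; bestMI <- ev$mi; bestOverlap <- ev$overlap
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    stepB <- stepB / 2
    stepT <- stepT / 2
  }

  tr <- do.call(rbind, trace[seq_len(nev)])
  colnames(tr) <- c("beta", "tx", "ty", "mi")
  new("RegistrationResult",
      uStar = rigidTransform(best[1], best[2], best[3]),
      trace = as.data.frame(tr), nEvals = nev, finalMI = bestMI,
      lowOverlap = bestOverlap < 0.10)
}

#' Resample by the recovered transform and fuse with the CT
#'
#' Convenience wrapper: warps the floating PET by the registration
#' optimum u* and alpha-blends it over the CT (see [fuseOverlay()]).
#'
#' @param pet,ct the image pair given to [registerImages()].
#' @param result the corresponding [RegistrationResult-class].
#' @param alpha PET overlay opacity in \code{[0, 1]}.
#' @return list with \code{petRegistered} ([Image2D-class]),
#'   \code{overlap} (logical matrix) and \code{fused} (H x W x 3 array).
#' @export
fuseAfterRegister <- function(pet, ct, result, alpha = 0.5) {
  stopifnot(is(result, "RegistrationResult"))
  rs <- resampleImage(pet, result@uStar, "bilinear", fill = 0)
  list(petRegistered = rs$image, overlap = rs$overlap,
       fused = fuseOverlay(rs$image, ct, alpha))
}
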