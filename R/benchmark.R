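#' Registration and segmentation benchmark on synthetic phantoms
#'
#' Runs the end-to-end study on a batch of phantoms: each phantom's PET
#' is displaced by a random rigid transform drawn within
#' \code{[-betaMax, betaMax]} rad and \code{[-tMax, tMax]} px, registered
#' back to the CT with [registerImages()], resampled by the recovered
#' transform, and segmented with [segmentHighUptake()]. Recovery error
#' is scored against the invert-consistent truth (the transform that
#' realigns the displaced PET) with [relativeError()], normalizing each
#' parameter by its search-range half-width taken from \code{config}.
#'
#' @param seeds integer vector of phantom seeds.
#' @param transformSeeds integer vector (same length) seeding the random
#'   displacement of each phantom.
#' @param size,nLesions,noiseSd,petBlurSigma phantom parameters, see
#'   [generatePhantom()].
#' @param betaMax,tMax displacement bounds (radians, pixels).
#' @param config a [RegistrationConfig-class].
#' @param segFraction fraction-of-max threshold for segmentation.
#' @return data.frame with one row per phantom: the true (realigning)
#'   and recovered parameters, MI at the identity and at the optimum,
#'   the normalized recovery error (percent), and segmentation scores
#'   against the generator's lesion mask.
#' @examples
#' \donttest{
#' bench <- phantomRegistrationBenchmark(seeds = 1:2, size = 64)
#' mean(bench$relative_error)
#' }
#' @export
phantomRegistrationBenchmark <- function(seeds = 1:20,
                                         transformSeeds = seeds + 1000L,
                                         size = 128, nLesions = 1,
                                         betaMax = 0.2, tMax = 8,
                                         noiseSd = 0.05, petBlurSigma = 2,
                                         config = registrationConfig(),
                                         segFraction = 0.4) {
  stopifnot(length(seeds) == length(transformSeeds))
  scale <- c(max(abs(config@betaRange)), max(abs(config@tRange)),
             max(abs(config@tRange)))
  rows <- lapply(seq_along(seeds), function(i) {
    disp <- randomRigidTransform(transformSeeds[i], betaMax, tMax)
    p <- transformParams(disp)
    ph <- generatePhantom(seeds[i], size = size, nLesions = nLesions,
                          beta = p[1], tx = p[2], ty = p[3],
                          noiseSd = noiseSd, petBlurSigma = petBlurSigma)
    res <- registerImages(ph@pet, ph@ct, config)
    truth <- transformParams(invertTransform(ph@trueTransform))
    est <- transformParams(res@uStar)
    idRow <- abs(res@trace$beta) < 1e-12 & abs(res@trace$tx) < 1e-12 &
      abs(res@trace$ty) < 1e-12
    reg <- resampleImage(ph@pet, res@uStar, "bilinear")$image
    seg <- segmentHighUptake(reg, "fraction_of_max", segFraction)
    m <- accuracyMetrics(seg, ph@lesionMask)
    data.frame(seed = seeds[i],
               beta_true = truth[1], tx_true = truth[2], ty_true = truth[3],
               beta_est = est[1], tx_est = est[2], ty_est = est[3],
               mi_identity = if (any(idRow)) res@trace$mi[idRow][1] else NA,
               mi_final = res@finalMI,
               relative_error = relativeError(est, truth, scale),
               pixel_accuracy = m[["pixel_accuracy"]],
               dice = m[["dice"]], jaccard = m[["jaccard"]])
  })
  do.call(rbind, rows)
}
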