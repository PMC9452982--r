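#' @import methods
NULL

#' Image2D: a 2D grayscale raster
#'
#' Container for a single-slice grayscale medical image: a numeric pixel
#' matrix (rows = first axis, columns = second axis), the physical pixel
#' spacing in millimetres, and a modality tag. The floating (PET) and
#' reference (CT) images of a registration problem are both held in this
#' class, as is the binary edge image derived from the CT.
#'
#' @slot pixels numeric matrix of finite intensities (arbitrary units).
#' @slot spacing numeric(2), physical size of a pixel (row, col) in mm.
#' @slot modality one of \code{"PET"}, \code{"CT"}, \code{"EDGE"},
#'   \code{"OTHER"}.
#'
#' @seealso [Image2D()] constructor, [readImage2D()], [writeImage2D()]
#' @exportClass Image2D
setClass("Image2D",
  representation(pixels = "matrix", spacing = "numeric",
                 modality = "character"),
  prototype(spacing = c(1, 1), modality = "OTHER"))

setValidity("Image2D", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else if (!all(is.finite(object@pixels)))
    msg <- c(msg, "'pixels' must be finite (no NA/NaN/Inf)")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be two positive numbers")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("PET", "CT", "EDGE", "OTHER"))
    msg <- c(msg, "'modality' must be one of PET, CT, EDGE, OTHER")
  if (is.null(msg)) TRUE else msg
})

#' QuantizedImage: integer gray-level labels of an image
#'
#' The result of equal-width intensity binning of an [Image2D] into
#' \code{levels} discrete gray levels, the random-variable form in which
#' images enter the joint histogram.
#'
#' @slot labels integer matrix with entries in \code{[0, levels-1]}.
#' @slot levels integer >= 2, number of gray levels.
#' @slot sourceRange numeric(2), the (min, max) intensities mapped onto
#'   the bins.
#'
#' @seealso [quantizeImage()], [jointHistogram()]
#' @exportClass QuantizedImage
setClass("QuantizedImage",
  representation(labels = "matrix", levels = "integer",
                 sourceRange = "numeric"))

setValidity("QuantizedImage", function(object) {
  msg <- NULL
  if (object@levels < 2L) msg <- c(msg, "'levels' must be >= 2")
  if (any(object@labels < 0L) || any(object@labels >= object@levels))
    msg <- c(msg, "labels must lie in [0, levels-1]")
  if (is.null(msg)) TRUE else msg
})

#' JointHistogram: co-located gray-level pair counts
#'
#' Counts n(u, d) of co-located pixel pairs with gray level u in the
#' floating image and d in the reference image; its normalisation by the
#' total pair count N estimates the joint probability j_UD(u, d), whose
#' row and column sums are the marginals j_U and j_D.
#'
#' @slot counts integer matrix, L_U x L_D pair counts.
#' @slot levels integer(2), (L_U, L_D).
#'
#' @seealso [jointHistogram()], [mutualInformation()], [jointProb()]
#' @exportClass JointHistogram
setClass("JointHistogram",
  representation(counts = "matrix", levels = "integer"))

setValidity("JointHistogram", function(object) {
  msg <- NULL
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (sum(object@counts) < 1) msg <- c(msg, "histogram must be nonempty")
  if (!identical(dim(object@counts), as.integer(object@levels)))
    msg <- c(msg, "dim(counts) must equal 'levels'")
  if (is.null(msg)) TRUE else msg
})

#' MIResult: entropies and mutual information of an image pair
#'
#' Marginal entropies H(U), H(D), joint entropy H(U,D) and the mutual
#' information I(U,D), all in bits (log base 2). I is computed directly
#' from the joint and marginal probabilities; the entropy identity
#' I = H(U) + H(D) - H(U,D) holds to numerical tolerance.
#'
#' @slot HU,HD,HUD entropies in bits.
#' @slot I mutual information in bits.
#'
#' @seealso [mutualInformation()]
#' @exportClass MIResult
setClass("MIResult",
  representation(HU = "numeric", HD = "numeric", HUD = "numeric",
                 I = "numeric"))

#' RigidTransform2D: rotation plus translation in the slice plane
#'
#' A rigid 2D transform: rotation by angle \code{beta} (radians) about
#' the image centre, followed by translation \code{(tx, ty)} in pixels
#' along the first (row) and second (column) image axes.
#'
#' @slot beta rotation angle in radians.
#' @slot tx,ty translations in pixels along the row and column axes.
#'
#' @seealso [rigidTransform()], [mapPoint()], [resampleImage()]
#' @exportClass RigidTransform2D
setClass("RigidTransform2D",
  representation(beta = "numeric", tx = "numeric", ty = "numeric"))

setValidity("RigidTransform2D", function(object) {
  if (!all(is.finite(c(object@beta, object@tx, object@ty))))
    "transform parameters must be finite" else TRUE
})

#' CNNTemplates: cellular-neural-network cloning templates
#'
#' The 3x3 feedback template A, 3x3 control template B and scalar bias z
#' of a (Chua--Yang) cellular neural network cell.
#'
#' @slot A 3x3 numeric feedback template (couples neighbour outputs).
#' @slot B 3x3 numeric control template (couples neighbour inputs).
#' @slot z numeric bias.
#'
#' @seealso [cnnTemplates()], [edgeTemplates()], [cnnEvolve()]
#' @exportClass CNNTemplates
setClass("CNNTemplates",
  representation(A = "matrix", B = "matrix", z = "numeric"))

setValidity("CNNTemplates", function(object) {
  msg <- NULL
  if (!identical(dim(object@A), c(3L, 3L)) ||
      !identical(dim(object@B), c(3L, 3L)))
    msg <- c(msg, "'A' and 'B' must be exactly 3x3")
  if (!all(is.finite(object@A)) || !all(is.finite(object@B)) ||
      !is.finite(object@z))
    msg <- c(msg, "template entries and bias must be finite")
  if (is.null(msg)) TRUE else msg
})

#' CNNState: state of a cellular neural network
#'
#' Cell states x, outputs y = 0.5(|x+1| - |x-1|) and the (fixed) input
#' plane u of a cellular neural network after integration.
#'
#' @slot x numeric matrix of cell states.
#' @slot y numeric matrix of outputs, always in \code{[-1, 1]}.
#' @slot u numeric matrix of inputs in \code{[-1, 1]}.
#'
#' @seealso [cnnEvolve()]
#' @exportClass CNNState
setClass("CNNState",
  representation(x = "matrix", y = "matrix", u = "matrix"))

#' RegistrationConfig: search settings for MI registration
#'
#' @slot levels integer, gray levels used to quantize the floating image
#'   (and the reference when \code{referenceMode = "ct_raw"}).
#' @slot referenceMode \code{"ct_edge"} (register against the CNN edge
#'   image of the CT; the reference is then binary) or \code{"ct_raw"}.
#' @slot betaRange,betaStep coarse grid over the rotation, radians.
#' @slot tRange,tStep coarse grid over each translation, pixels.
#' @slot tolBeta,tolT refinement stops once the step sizes drop below
#'   these tolerances (radians, pixels).
#' @slot seed integer, reserved for randomized multi-start strategies.
#'
#' @seealso [registrationConfig()], [registerImages()]
#' @exportClass RegistrationConfig
setClass("RegistrationConfig",
  representation(levels = "integer", referenceMode = "character",
                 betaRange = "numeric", betaStep = "numeric",
                 tRange = "numeric", tStep = "numeric",
                 tolBeta = "numeric", tolT = "numeric", seed = "integer"))

setValidity("RegistrationConfig", function(object) {
  msg <- NULL
  if (object@levels < 2L) msg <- c(msg, "'levels' must be >= 2")
  if (!object@referenceMode %in% c("ct_edge", "ct_raw"))
    msg <- c(msg, "'referenceMode' must be 'ct_edge' or 'ct_raw'")
  if (diff(object@betaRange) < 0 || diff(object@tRange) < 0)
    msg <- c(msg, "grid ranges must be nondecreasing")
  if (object@betaStep <= 0 || object@tStep <= 0)
    msg <- c(msg, "grid steps must be positive")
  if (object@tolBeta <= 0 || object@tolT <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (is.null(msg)) TRUE else msg
})

#' RegistrationResult: optimum and trace of an MI registration
#'
#' @slot uStar the recovered [RigidTransform2D] (the transform that,
#'   applied to the floating image, maximizes MI with the reference).
#' @slot trace data.frame of every evaluation: beta, tx, ty, mi.
#' @slot nEvals integer, number of MI evaluations.
#' @slot finalMI mutual information (bits) at \code{uStar}.
#' @slot lowOverlap logical, TRUE if the overlap at the optimum covered
#'   less than 10\% of the pixels.
#'
#' @seealso [registerImages()]
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(uStar = "RigidTransform2D", trace = "data.frame",
                 nEvals = "integer", finalMI = "numeric",
                 lowOverlap = "logical"))

#' SegmentationResult: a high-uptake mask
#'
#' @slot mask binary (0/1) matrix, 1 = high uptake.
#' @slot thresholdUsed the absolute intensity threshold applied.
#' @slot nForeground number of foreground pixels.
#'
#' @seealso [segmentHighUptake()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(mask = "matrix", thresholdUsed = "numeric",
                 nForeground = "integer"))

#' Phantom: a co-registered synthetic CT/PET pair with ground truth
#'
#' @slot ct CT-like [Image2D] (sharp bone structures, piecewise-constant
#'   soft tissue).
#' @slot pet PET-like [Image2D] (smooth uptake, blurred hot lesions,
#'   additive noise), displaced from the CT frame by
#'   \code{trueTransform}.
#' @slot trueTransform the [RigidTransform2D] applied to the PET.
#' @slot lesionMask binary matrix of true lesion extent in the CT frame.
#' @slot seed integer seed that reproduces the phantom bit-identically.
#'
#' @seealso [generatePhantom()]
#' @exportClass Phantom
setClass("Phantom",
  representation(ct = "Image2D", pet = "Image2D",
                 trueTransform = "RigidTransform2D",
                 lesionMask = "matrix", seed = "integer"))

#' EfficacyTally: RECIST response counts and percentages
#'
#' Counts and half-up-rounded percentages of the four RECIST categories
#' (CR, PR, SD, PD) among evaluable patients at a treatment checkpoint.
#'
#' @slot checkpoint integer treatment-cycle checkpoint (e.g. 3 or 6).
#' @slot n total evaluable patients at the checkpoint.
#' @slot counts named integer vector over CR, PR, SD, PD.
#' @slot percentages named numeric vector, count/n*100 rounded half-up
#'   to one decimal.
#'
#' @seealso [tallyResponses()]
#' @exportClass EfficacyTally
setClass("EfficacyTally",
  representation(checkpoint = "integer", n = "integer",
                 counts = "integer", percentages = "numeric"))

setValidity("EfficacyTally", function(object) {
  msg <- NULL
  if (!identical(names(object@counts), c("CR", "PR", "SD", "PD")))
    msg <- c(msg, "'counts' must be named CR, PR, SD, PD")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "counts must sum to n")
  if (is.null(msg)) TRUE else msg
})
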