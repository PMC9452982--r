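#' Construct an Image2D
#'
#' @param pixels numeric matrix of finite intensities.
#' @param spacing numeric(2) physical pixel size (row, col) in mm.
#' @param modality one of \code{"PET"}, \code{"CT"}, \code{"EDGE"},
#'   \code{"OTHER"}.
#' @return an [Image2D-class] object.
#' @examples
#' img <- Image2D(matrix(runif(64), 8, 8), modality = "CT")
#' dim(img)
#' @export
Image2D <- function(pixels, spacing = c(1, 1), modality = "OTHER") {
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  new("Image2D", pixels = pixels, spacing = as.numeric(spacing),
      modality = modality)
}

#' @rdname Image2D-class
#' @export
setMethod("pixels", "Image2D", function(object) object@pixels)

#' @rdname Image2D-class
#' @export
setMethod("spacing", "Image2D", function(object) object@spacing)

#' @rdname Image2D-class
#' @export
setMethod("modality", "Image2D", function(object) object@modality)

#' @rdname Image2D-class
#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  rg <- range(object@pixels)
  cat(sprintf("Image2D [%s] %d x %d, spacing %.3g x %.3g mm, range [%.4g, %.4g]\n",
              object@modality, d[1], d[2], object@spacing[1],
              object@spacing[2], rg[1], rg[2]))
})

#' Read a 2D grayscale image
#'
#' Reads a single-slice grayscale raster from NIfTI (via RNifti), 8/16-bit
#' grayscale PNG, or raw float32 with a plain-text sidecar (see
#' [writeImage2D()]). Intensities are returned as stored; no rescaling is
#' applied. If \code{format} is missing it is inferred from the file
#' extension.
#'
#' @param path file to read.
#' @param format \code{"nifti"}, \code{"png"} or \code{"raw"}.
#' @param modality modality tag for the returned image.
#' @param slice for a 3D NIfTI volume, the index of the slice (third
#'   dimension) to extract; reading a volume without \code{slice} is an
#'   error.
#' @return an [Image2D-class].
#' @seealso [writeImage2D()]
#' @export
readImage2D <- function(path, format = c("auto", "nifti", "png", "raw"),
                        modality = "OTHER", slice = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path) && format != "raw")
    stop("cannot read image: file not found: ", path)
  px <- switch(format,
    nifti = {
      vol <- tryCatch(as.array(RNifti::readNifti(path)),
                      error = function(e)
                        stop("cannot read NIfTI file ", path, ": ",
                             conditionMessage(e)))
      vol <- drop(vol)
      if (length(dim(vol)) == 3L) {
        if (is.null(slice))
          stop("NIfTI file ", path,
               " is a 3D volume; supply 'slice' to extract a 2D slice")
        vol <- vol[, , slice]
      }
      if (length(dim(vol)) != 2L)
        stop("NIfTI file ", path, " does not hold a 2D slice")
      vol
    },
    png = {
      arr <- tryCatch(png::readPNG(path),
                      error = function(e)
                        stop("cannot read PNG file ", path, ": ",
                             conditionMessage(e)))
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # gray from RGB(A)
      arr
    },
    raw = readRawImage(path))
  Image2D(px, modality = modality)
}

#' Write a 2D grayscale image
#'
#' NIfTI is written as float64 and raw as float32 (both round-trip
#' losslessly through [readImage2D()] for float32-representable data);
#' PNG is written 16-bit with intensities min-max scaled to \code{[0, 1]}
#' (lossy for general floating-point data). The raw format writes
#' \code{<path>} (row-major float32, little-endian) plus a sidecar
#' \code{<path>.dim} holding "nrow ncol".
#'
#' @param img an [Image2D-class].
#' @param path output file; parent directory must exist.
#' @param format \code{"nifti"}, \code{"png"} or \code{"raw"}
#'   (\code{"auto"}: from extension).
#' @return \code{invisible(path)}.
#' @export
writeImage2D <- function(img, path,
                         format = c("auto", "nifti", "png", "raw")) {
  stopifnot(is(img, "Image2D"))
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!dir.exists(dirname(path)))
    stop("cannot write image: directory does not exist: ", dirname(path))
  px <- img@pixels
  switch(format,
    nifti = RNifti::writeNifti(
      RNifti::asNifti(px, datatype = "double"), path),
    png = {
      rg <- range(px)
      sc <- if (diff(rg) > 0) (px - rg[1]) / diff(rg) else px * 0
      png::writePNG(sc, path, dpi = NULL)
    },
    raw = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")
      writeLines(paste(nrow(px), ncol(px)), paste0(path, ".dim"))
    })
  invisible(path)
}

guessFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
  else "raw"
}

readRawImage <- function(path) {
  sidecar <- paste0(path, ".dim")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("raw image needs both ", path, " and sidecar ", sidecar)
  shape <- as.integer(strsplit(trimws(readLines(sidecar)[1]), "\\s+")[[1]])
  if (length(shape) != 2L || any(shape < 1L))
    stop("sidecar ", sidecar, " must hold 'nrow ncol'")
  vals <- readBin(path, what = "numeric", n = prod(shape), size = 4L,
                  endian = "little")
  if (length(vals) != prod(shape))
    stop("raw file ", path, " holds ", length(vals),
         " values, expected ", prod(shape))
  matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Quantize an image to discrete gray levels
#'
#' Equal-width binning of the observed intensity range \code{[min, max]}
#' (or a supplied \code{sourceRange}) into \code{levels} bins: the
#' minimum maps to bin 0, the maximum to bin \code{levels - 1}, and a
#' constant image maps wholly to bin 0. Quantization is monotone in
#' intensity, and equal-width binning over the observed range makes the
#' downstream mutual information invariant to affine rescaling of either
#' image's intensities.
#'
#' @param img an [Image2D-class].
#' @param levels integer >= 2, number of gray levels.
#' @param sourceRange optional numeric(2) fixing the intensity range to
#'   bin (values outside are clamped to the end bins); by default the
#'   image's own range. Fixing the range keeps bins comparable across
#'   resampled versions of the same image.
#' @return a [QuantizedImage-class].
#' @examples
#' q <- quantizeImage(Image2D(matrix(0:63, 8, 8)), levels = 4)
#' table(labels2d(q))
#' @export
quantizeImage <- function(img, levels, sourceRange = NULL) {
  stopifnot(is(img, "Image2D"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("'levels' must be an integer >= 2")
  px <- img@pixels
  rg <- if (is.null(sourceRange)) range(px) else as.numeric(sourceRange)
  lab <- quantizeValues(px, levels, rg)
  new("QuantizedImage", labels = lab, levels = levels, sourceRange = rg)
}

# shared by quantizeImage and the registration inner loop (plain matrix in)
quantizeValues <- function(px, levels, rg) {
  if (diff(rg) <= 0) {
    lab <- matrix(0L, nrow(px), ncol(px))
  } else {
    lab <- floor((px - rg[1]) / diff(rg) * levels)
    lab[lab < 0] <- 0
    lab[lab >= levels] <- levels - 1L  # max intensity -> top bin
    storage.mode(lab) <- "integer"
  }
  lab
}

#' @rdname QuantizedImage-class
#' @export
setMethod("labels2d", "QuantizedImage", function(object) object@labels)

#' @rdname QuantizedImage-class
#' @export
setMethod("grayLevels", "QuantizedImage", function(object) object@levels)

setMethod("show", "QuantizedImage", function(object) {
  cat(sprintf("QuantizedImage %d x %d, %d levels, source range [%.4g, %.4g]\n",
              nrow(object@labels), ncol(object@labels), object@levels,
              object@sourceRange[1], object@sourceRange[2]))
})
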