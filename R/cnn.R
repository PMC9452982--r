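#' Construct CNN cloning templates
#'
#' @param A 3x3 numeric feedback template.
#' @param B 3x3 numeric control template.
#' @param z numeric bias.
#' @return a [CNNTemplates-class].
#' @seealso [edgeTemplates()] for the edge-detection configuration.
#' @export
cnnTemplates <- function(A, B, z) {
  new("CNNTemplates", A = matrix(as.numeric(A), 3, 3),
      B = matrix(as.numeric(B), 3, 3), z = as.numeric(z))
}

#' Edge-detection templates
#'
#' The classical cellular-neural-network edge-detection configuration:
#' centre-only feedback (a00 = 1), Laplacian-style control template with
#' centre 8 and -1 surround, bias z = -1. At steady state a cell's
#' output saturates to +1 (edge) only where the local input contrast
#' term B*u exceeds 1, and to -1 elsewhere.
#'
#' @return a [CNNTemplates-class].
#' @export
edgeTemplates <- function() {
  cnnTemplates(A = diag(0, 3) + c(0, 0, 0, 0, 1, 0, 0, 0, 0),
               B = matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3),
               z = -1)
}

#' Read CNN templates from a plain-text config
#'
#' Format: nine A values (row-major), nine B values, then z, whitespace
#' separated across any number of lines; lines starting with '#' are
#' ignored.
#'
#' @param path text file to read.
#' @return a [CNNTemplates-class].
#' @export
readTemplates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  vals <- as.numeric(unlist(strsplit(trimws(paste(lines, collapse = " ")),
                                     "\\s+")))
  if (length(vals) != 19L || any(!is.finite(vals)))
    stop("template file must hold 19 finite numbers (9 A, 9 B, z)")
  cnnTemplates(matrix(vals[1:9], 3, 3, byrow = TRUE),
               matrix(vals[10:18], 3, 3, byrow = TRUE), vals[19])
}

#' Map image intensities into the CNN input range [-1, 1]
#'
#' Linear map taking the minimum intensity to -1 and the maximum to +1
#' (so the midpoint maps to 0); a constant image maps to all -1, the
#' background/white convention under which a featureless input excites
#' no cell.
#'
#' @param img an [Image2D-class] or numeric matrix.
#' @return numeric matrix in \code{[-1, 1]}.
#' @export
normalizeToCNNRange <- function(img) {
  px <- if (is(img, "Image2D")) img@pixels else as.matrix(img)
  rg <- range(px)
  if (diff(rg) <= 0) return(matrix(-1, nrow(px), ncol(px)))
  2 * (px - rg[1]) / diff(rg) - 1
}

# 3x3 cross-correlation of `plane` with template `tmpl`.
# boundary "replicate": virtual cells copy the nearest grid cell;
# boundary "zero": virtual cells are 0 (Dirichlet).
conv3x3 <- function(plane, tmpl, boundary = "replicate") {
  nr <- nrow(plane); nc <- ncol(plane)
  if (boundary == "replicate") {
    padded <- plane[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  } else {
    padded <- matrix(0, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- plane
  }
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    w <- tmpl[di + 1, dj + 1]
    if (w != 0)
      out <- out + w * padded[di + seq_len(nr), dj + seq_len(nc)]
  }
  out
}

# clamp guards against last-bit rounding of the two subtractions, so the
# saturation bound |y| <= 1 holds exactly
cnnOutput <- function(x) pmin(pmax(0.5 * (abs(x + 1) - abs(x - 1)), -1), 1)

#' Integrate the cellular neural network
#'
#' Forward-Euler integration of the Chua--Yang cell dynamics
#' \deqn{dx_{ij}/dt = -x_{ij} + (A * y)_{ij} + (B * u)_{ij} + z}
#' with output nonlinearity \eqn{y = 0.5(|x+1| - |x-1|)}, on a fixed
#' input plane \code{u}. Cells outside the grid are supplied by the
#' boundary rule: \code{"replicate"} (default; virtual cells copy their
#' nearest grid cell, so uniform regions touching the border excite no
#' response) or \code{"zero"} (Dirichlet).
#'
#' @param input numeric matrix in \code{[-1, 1]}, at least 3x3.
#' @param templates a [CNNTemplates-class].
#' @param step Euler step (time units), > 0.
#' @param duration total integration time, >= step.
#' @param initialState numeric matrix of initial cell states, or
#'   \code{"copy-input"} (default) to start from the input plane.
#' @param boundary \code{"replicate"} or \code{"zero"}.
#' @return a [CNNState-class] holding the final states and outputs.
#' @examples
#' u <- matrix(-1, 8, 8); u[4:5, 4:5] <- 1
#' st <- cnnEvolve(u, edgeTemplates())
#' range(st@y)
#' @export
cnnEvolve <- function(input, templates, step = 0.1, duration = 10,
                      initialState = "copy-input",
                      boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  input <- as.matrix(input)
  if (nrow(input) < 3L || ncol(input) < 3L)
    stop("CNN input must be at least 3x3")
  if (!is.finite(step) || step <= 0)
    stop("'step' must be a positive number")
  if (duration < step)
    stop("'duration' must be >= 'step'")
  if (!all(is.finite(templates@A)) || !all(is.finite(templates@B)))
    stop("template entries must be finite")
  x <- if (identical(initialState, "copy-input")) input
       else as.matrix(initialState)
  # B*u + z is constant along the trajectory: precompute once
  drive <- conv3x3(input, templates@B, boundary) + templates@z
  feedbackOnlyCenter <- all(templates@A[-5] == 0)
  a00 <- templates@A[2, 2]
  nSteps <- floor(duration / step + 1e-9)
  for (k in seq_len(nSteps)) {
    y <- cnnOutput(x)
    Ay <- if (feedbackOnlyCenter) a00 * y
          else conv3x3(y, templates@A, boundary)
    x <- x + step * (-x + Ay + drive)
  }
  new("CNNState", x = x, y = cnnOutput(x), u = input)
}

setMethod("show", "CNNState", function(object) {
  cat(sprintf("CNNState %d x %d, state range [%.3g, %.3g], %d cells at y=+1\n",
              nrow(object@x), ncol(object@x), min(object@x), max(object@x),
              sum(object@y > 0)))
})

#' Extract the edge image of a CT slice
#'
#' Normalizes the CT to the CNN input range, runs the edge-template
#' cellular neural network to steady state, and thresholds the output at
#' 0: cells with y > 0 are edge pixels (value 1), the rest non-edge
#' (value 0). The PET counterpart is deliberately not edge-extracted —
#' its low resolution and blurred boundaries make PET edges unreliable —
#' so registration pairs the PET gray values with this binary CT edge
#' reference.
#'
#' @param ct a CT [Image2D-class].
#' @param templates CNN templates, default [edgeTemplates()].
#' @param step,duration Euler integration settings (see [cnnEvolve()]).
#' @param boundary boundary rule, see [cnnEvolve()].
#' @return binary [Image2D-class] with modality \code{"EDGE"}.
#' @examples
#' ct <- Image2D(cbind(matrix(0, 16, 8), matrix(255, 16, 8)))
#' which(pixels(edgeExtract(ct)) == 1, arr.ind = TRUE)[1:3, ]
#' @export
edgeExtract <- function(ct, templates = edgeTemplates(), step = 0.1,
                        duration = 10, boundary = c("replicate", "zero")) {
  stopifnot(is(ct, "Image2D"))
  boundary <- match.arg(boundary)
  u <- normalizeToCNNRange(ct)
  st <- cnnEvolve(u, templates, step = step, duration = duration,
                  boundary = boundary)
  Image2D((st@y > 0) * 1, spacing = ct@spacing, modality = "EDGE")
}
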