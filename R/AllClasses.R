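#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CornerDx, .registration = TRUE
NULL

#' BrainSlice: a raw 2-D grayscale brain slice
#'
#' Container for one unprocessed slice: an integer-valued intensity matrix
#' together with its bit depth (8 for typical CT exports, 16 for MRI), so
#' that intensity rescaling to \[0,1\] can use the bit-depth maximum rather
#' than the per-image maximum and CT/MRI are treated uniformly.
#'
#' @slot pixels numeric matrix of non-negative intensities (rows are the
#'   vertical axis).
#' @slot bitDepth integer, 8 or 16.
#' @slot id character identifier of the source.
#' @export
setClass("BrainSlice",
  representation(pixels = "matrix", bitDepth = "integer", id = "character"),
  prototype(bitDepth = 8L, id = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@pixels))
      msg <- c(msg, "pixels must be a numeric matrix")
    if (any(dim(object@pixels) < 2L))
      msg <- c(msg, "image must be at least 2x2")
    if (!object@bitDepth %in% c(8L, 16L))
      msg <- c(msg, "bitDepth must be 8 or 16")
    if (is.numeric(object@pixels)) {
      if (any(object@pixels < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be non-negative")
      if (any(object@pixels > 2^object@bitDepth - 1, na.rm = TRUE))
        msg <- c(msg, "intensities exceed the bit-depth range")
    }
    if (is.null(msg)) TRUE else msg
  })

#' NormalizedImage: a size- and intensity-normalized slice
#'
#' The output of [normalizeImage()]: only the intracranial portion is
#' retained (everything else is 0), the principal axis is vertical, the
#' mask bounding box has been resized to a common (Row, Column) grid, and
#' intensities are in \[0,1\] after division by the bit-depth maximum.
#'
#' @slot gi numeric matrix with values in \[0,1\].
#' @slot id character identifier.
#' @export
setClass("NormalizedImage",
  representation(gi = "matrix", id = "character"),
  prototype(id = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@gi))
      msg <- c(msg, "gi must be numeric")
    else if (any(object@gi < 0) || any(object@gi > 1))
      msg <- c(msg, "gi values must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
  })

#' GradientField: smoothed gradient magnitudes of a normalized image
#'
#' Gradient magnitude (Gaussian smoothing then 3x3 Sobel), plus the
#' magnitude after non-maximum suppression along the quantized gradient
#' direction, which every threshold layer reuses.
#'
#' @slot mag numeric matrix of gradient magnitudes.
#' @slot nms numeric matrix; `mag` where the pixel is a directional local
#'   maximum, 0 elsewhere.
#' @slot maxMag maximum of `mag` (the M that scales all thresholds).
#' @slot sigma smoothing sigma used.
#' @export
setClass("GradientField",
  representation(mag = "matrix", nms = "matrix", maxMag = "numeric",
                 sigma = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@mag < 0)) msg <- c(msg, "magnitudes must be non-negative")
    if (!isTRUE(all.equal(object@maxMag, max(object@mag))))
      msg <- c(msg, "maxMag must equal max(mag)")
    if (!identical(dim(object@mag), dim(object@nms)))
      msg <- c(msg, "mag and nms must be congruent")
    if (is.null(msg)) TRUE else msg
  })

#' ThresholdSchedule: the descending hysteresis double-threshold schedule
#'
#' One row per layer i: the pixel-fraction parameter R^i, the selected
#' histogram bin index s^i (smallest s with cumulative count >= R^i times
#' the pixel count), and the derived pair highTh^i = s^i/Bn,
#' lowTh^i = rTh * highTh^i. Thresholds are fractions of the maximum
#' gradient magnitude M.
#'
#' @slot R numeric vector, strictly decreasing fractions.
#' @slot s integer vector of bin indices in 1..bn.
#' @slot highTh,lowTh numeric vectors of threshold fractions.
#' @slot bn integer, number of histogram bins.
#' @slot rTh numeric, low/high threshold ratio.
#' @export
setClass("ThresholdSchedule",
  representation(R = "numeric", s = "integer", highTh = "numeric",
                 lowTh = "numeric", bn = "integer", rTh = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@R)
    if (length(object@s) != n || length(object@highTh) != n ||
        length(object@lowTh) != n)
      msg <- c(msg, "R, s, highTh, lowTh must have equal length")
    if (n > 1 && any(diff(object@R) >= 0))
      msg <- c(msg, "R must be strictly decreasing")
    if (any(object@s < 1L) || any(object@s > object@bn))
      msg <- c(msg, "s out of 1..bn")
    if (n > 1 && any(diff(object@highTh) > 1e-12))
      msg <- c(msg, "highTh must be non-increasing")
    if (any(abs(object@highTh - object@s / object@bn) > 1e-12))
      msg <- c(msg, "highTh must equal s/bn")
    if (any(abs(object@lowTh - object@rTh * object@highTh) > 1e-12))
      msg <- c(msg, "lowTh must equal rTh*highTh")
    if (is.null(msg)) TRUE else msg
  })

#' TextureImage: the multilayer texture image (MTI)
#'
#' A grid whose value at a pixel is 1/i when the pixel is first claimed by
#' the edge map of threshold layer i (first-layer priority), and 0 for
#' background. Nonzero values therefore form the set \{1, 1/2, ..., 1/N\}
#' and encode region significance: strong-threshold textures score 1.
#'
#' @slot values numeric matrix over \{0\} union \{1/i\}.
#' @slot nLayers integer N, the number of schedule layers.
#' @slot schedule the [ThresholdSchedule-class] that generated the layers.
#' @slot id character identifier of the source image.
#' @export
setClass("TextureImage",
  representation(values = "matrix", nLayers = "integer",
                 schedule = "ThresholdSchedule", id = "character"),
  prototype(id = NA_character_),
  validity = function(object) {
    msg <- NULL
    v <- object@values[object@values != 0]
    if (length(v)) {
      layer <- round(1 / v)
      if (any(layer < 1) || any(layer > object@nLayers) ||
          any(abs(v - 1 / layer) > 1e-12))
        msg <- c(msg, "nonzero values must be exactly 1/i for i in 1..nLayers")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CornerSet: Harris corners with importance values
#'
#' Corners detected on an MTI at response threshold theta. Each corner is a
#' (row, col) position (1-based) with its importance value, the MTI value
#' at that pixel; background pixels can never be corners, so importance is
#' always positive. Corners are stored in row-major order (by row, then
#' column) and positions are unique.
#'
#' @slot coords integer matrix with columns `m` (row) and `n` (col).
#' @slot importance numeric vector in (0,1\].
#' @slot response numeric vector of normalized Harris responses.
#' @slot theta numeric, the response threshold used.
#' @slot dim integer(2), dimensions of the source MTI.
#' @slot id character identifier.
#' @export
setClass("CornerSet",
  representation(coords = "matrix", importance = "numeric",
                 response = "numeric", theta = "numeric", dim = "integer",
                 id = "character"),
  prototype(theta = NA_real_, id = NA_character_),
  validity = function(object) {
    msg <- NULL
    k <- nrow(object@coords)
    if (ncol(object@coords) != 2L)
      msg <- c(msg, "coords must have two columns (m, n)")
    if (length(object@importance) != k)
      msg <- c(msg, "importance length must match the number of corners")
    if (any(object@importance <= 0))
      msg <- c(msg, "corner importance must be positive")
    if (k && length(object@dim) == 2L &&
        (any(object@coords[, 1] < 1L) || any(object@coords[, 1] > object@dim[1]) ||
         any(object@coords[, 2] < 1L) || any(object@coords[, 2] > object@dim[2])))
      msg <- c(msg, "corner coordinates out of image bounds")
    if (k && anyDuplicated(object@coords))
      msg <- c(msg, "duplicate corner positions")
    if (is.null(msg)) TRUE else msg
  })

#' CornerMatching: the final one-to-one matched corner pair sequence
#'
#' The result of [finalMatches()]: a one-to-one subset of the initial
#' (mobility-filtered) candidate pairs with maximum cardinality and, among
#' maximum-cardinality matchings, minimum total Euclidean distance.
#'
#' @slot pairs data.frame with columns `left`, `right` (corner indices into
#'   the two sequences) and `dis` (Euclidean distance in pixels).
#' @slot totalDis numeric, sum of `dis`.
#' @slot nLeft,nRight integer, the full corner counts |C| and |C'| of the
#'   two images (including unmatched corners).
#' @export
setClass("CornerMatching",
  representation(pairs = "data.frame", totalDis = "numeric",
                 nLeft = "integer", nRight = "integer"),
  validity = function(object) {
    msg <- NULL
    p <- object@pairs
    if (!all(c("left", "right", "dis") %in% names(p)))
      msg <- c(msg, "pairs must have columns left, right, dis")
    else {
      if (anyDuplicated(p$left) || anyDuplicated(p$right))
        msg <- c(msg, "matching must be one-to-one")
      if (any(p$dis < 0)) msg <- c(msg, "distances must be non-negative")
      if (!isTRUE(all.equal(object@totalDis, sum(p$dis))))
        msg <- c(msg, "totalDis must equal sum(pairs$dis)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CornerClassifier: a trained similarity-KNN corner classifier
#'
#' Stores the labeled training corner sequences (detected at the selected
#' theta), the selected (thetaC, kC), the similarity parameters, the
#' normalization target dimensions and the cross-validation accuracy grid.
#'
#' @slot training list of [CornerSet-class] objects.
#' @slot labels character vector ("Normal"/"Abnormal"), parallel to
#'   `training`.
#' @slot thetaC,kC the selected corner-response threshold and neighbour
#'   count.
#' @slot simParams list of similarity parameters (see [simParams()]).
#' @slot targetDims integer(2) normalization target (Row, Column).
#' @slot cvGrid data.frame with columns theta, k, accuracy.
#' @export
setClass("CornerClassifier",
  representation(training = "list", labels = "character", thetaC = "numeric",
                 kC = "integer", simParams = "list", targetDims = "integer",
                 cvGrid = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@training) != length(object@labels))
      msg <- c(msg, "training and labels must be parallel")
    if (length(object@training) == 0L)
      msg <- c(msg, "classifier must contain training items")
    if (length(object@kC) != 1L || object@kC < 1L ||
        object@kC > length(object@training))
      msg <- c(msg, "kC must lie in 1..number of training items")
    if (!all(object@labels %in% c("Normal", "Abnormal")))
      msg <- c(msg, "labels must be 'Normal' or 'Abnormal'")
    if (is.null(msg)) TRUE else msg
  })
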