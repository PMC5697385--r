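#' Number of corners in a corner set
#' @param x a [CornerSet-class]
#' @return integer count
#' @export
setGeneric("nCorners", function(x) standardGeneric("nCorners"))

#' Corner coordinates
#' @param x a [CornerSet-class]
#' @return integer matrix with columns `m`, `n` (1-based row/col)
#' @export
setGeneric("cornerCoords", function(x) standardGeneric("cornerCoords"))

#' Importance values of corners
#' @param x a [CornerSet-class]
#' @return numeric vector of MTI values at the corners
#' @export
setGeneric("importanceValues", function(x) standardGeneric("importanceValues"))

#' Corner mobility
#'
#' Mobility is the positional slack allowed when matching a corner between
#' two images: the reciprocal of the importance value, so a layer-i corner
#' may move i pixels. Important corners move less.
#'
#' @param x a [CornerSet-class] or a numeric vector of importance values
#' @param ... unused
#' @return numeric vector of mobilities (pixels)
#' @export
setGeneric("mobility", function(x, ...) standardGeneric("mobility"))

#' Number of layers of a texture image
#' @param x a [TextureImage-class]
#' @return integer N
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' MTI value grid
#' @param x a [TextureImage-class]
#' @return numeric matrix over \{0\} union \{1/i\}
#' @export
setGeneric("mtiValues", function(x) standardGeneric("mtiValues"))

#' Threshold schedule of a texture image
#' @param x a [TextureImage-class]
#' @return a [ThresholdSchedule-class]
#' @export
setGeneric("thresholdSchedule", function(x) standardGeneric("thresholdSchedule"))

#' Matched pairs of a corner matching
#' @param x a [CornerMatching-class]
#' @return data.frame with columns left, right, dis
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' Total distance of a corner matching
#' @param x a [CornerMatching-class]
#' @return numeric, the sum of pair distances
#' @export
setGeneric("totalDistance", function(x) standardGeneric("totalDistance"))

#' Predict the label of a new image or corner set
#' @param object a trained [CornerClassifier-class]
#' @param newdata a [CornerSet-class], [TextureImage-class],
#'   [NormalizedImage-class] or [BrainSlice-class]
#' @param ... unused
#' @return character label, "Normal" or "Abnormal"
#' @export
setGeneric("predictLabel", function(object, newdata, ...)
  standardGeneric("predictLabel"))
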