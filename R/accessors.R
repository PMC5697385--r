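#' @rdname nCorners
setMethod("nCorners", "CornerSet", function(x) nrow(x@coords))

#' @rdname cornerCoords
setMethod("cornerCoords", "CornerSet", function(x) x@coords)

#' @rdname importanceValues
setMethod("importanceValues", "CornerSet", function(x) x@importance)

#' @rdname mobility
setMethod("mobility", "CornerSet", function(x, ...) mobility(x@importance))

#' @rdname mobility
setMethod("mobility", "numeric", function(x, ...) {
  if (any(x <= 0))
    stop("corner without importance: importance values must be positive")
  1 / x
})

#' @rdname nLayers
setMethod("nLayers", "TextureImage", function(x) x@nLayers)

#' @rdname mtiValues
setMethod("mtiValues", "TextureImage", function(x) x@values)

#' @rdname thresholdSchedule
setMethod("thresholdSchedule", "TextureImage", function(x) x@schedule)

#' @rdname matchedPairs
setMethod("matchedPairs", "CornerMatching", function(x) x@pairs)

#' @rdname totalDistance
setMethod("totalDistance", "CornerMatching", function(x) x@totalDis)

setMethod("dim", "NormalizedImage", function(x) dim(x@gi))
setMethod("dim", "TextureImage", function(x) dim(x@values))
setMethod("dim", "BrainSlice", function(x) dim(x@pixels))

setMethod("show", "BrainSlice", function(object) {
  cat(sprintf("BrainSlice '%s': %d x %d, %d-bit\n", object@id,
              nrow(object@pixels), ncol(object@pixels), object@bitDepth))
})

setMethod("show", "NormalizedImage", function(object) {
  cat(sprintf("NormalizedImage '%s': %d x %d, range [%.3f, %.3f]\n",
              object@id, nrow(object@gi), ncol(object@gi),
              min(object@gi), max(object@gi)))
})

setMethod("show", "ThresholdSchedule", function(object) {
  cat(sprintf("ThresholdSchedule: %d layers, Bn = %d, rTh = %.2f\n",
              length(object@R), object@bn, object@rTh))
  print(as.data.frame(object))
})

#' @export
as.data.frame.ThresholdSchedule <- function(x, ...) {
  data.frame(R = x@R, s = x@s, highTh = x@highTh, lowTh = x@lowTh)
}

setMethod("show", "TextureImage", function(object) {
  nz <- sum(object@values != 0)
  cat(sprintf("TextureImage '%s': %d x %d, %d layers, %d texture pixels (%.1f%%)\n",
              object@id, nrow(object@values), ncol(object@values),
              object@nLayers, nz, 100 * nz / length(object@values)))
})

setMethod("show", "CornerSet", function(object) {
  cat(sprintf("CornerSet '%s': %d corners (theta = %s)\n", object@id,
              nCorners(object), format(object@theta)))
  if (nCorners(object)) {
    tab <- table(factor(round(1 / object@importance)))
    cat("  corners per layer:",
        paste(sprintf("L%s:%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

setMethod("show", "CornerMatching", function(object) {
  cat(sprintf("CornerMatching: %d pairs (|C| = %d, |C'| = %d), total distance %.3f\n",
              nrow(object@pairs), object@nLeft, object@nRight, object@totalDis))
})

setMethod("show", "CornerClassifier", function(object) {
  cat(sprintf("CornerClassifier: %d training images (%s), thetaC = %.3g, kC = %d\n",
              length(object@training),
              paste(sprintf("%s: %d", names(table(object@labels)),
                            as.integer(table(object@labels))), collapse = ", "),
              object@thetaC, object@kC))
})
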