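#' Build the multilayer texture image (MTI)
#'
#' Runs the full texture-extraction chain on a normalized image: smoothed
#' Sobel gradient, 64-bin magnitude histogram, descending threshold
#' schedule (R = r1, r1 - step, ..., 0), one Canny-style edge map per
#' threshold pair, and first-layer-priority fusion: a pixel takes the
#' value 1/i for the smallest layer index i whose edge map contains it,
#' and 0 when no layer passes it (background, no diagnostic content).
#' Consecutive layers with identical thresholds produce identical edge
#' maps and contribute no new pixels, so they are skipped.
#'
#' Because all thresholds are fractions of the per-image maximum gradient
#' magnitude, the MTI is invariant under global rescaling of the raw
#' intensities — the mechanism behind the method's robustness to the
#' different intensity ranges of CT (256 levels) and MRI (65536 levels).
#'
#' @param gi a [NormalizedImage-class] or numeric matrix in \[0,1\]
#' @param bn histogram bins (study value 64)
#' @param r1 first pixel fraction (study value 0.8)
#' @param step fraction decrement (study value 0.1)
#' @param rTh low/high threshold ratio (study value 0.3)
#' @param sigma gradient smoothing sigma (pixels)
#' @param includeZero include the terminal R = 0 layer
#' @return a [TextureImage-class]
#' @export
buildMTI <- function(gi, bn = 64L, r1 = 0.8, step = 0.1, rTh = 0.3,
                     sigma = 1.4, includeZero = TRUE) {
  id <- if (is(gi, "NormalizedImage")) gi@id else NA_character_
  gf <- computeGradient(gi, sigma = sigma)
  h <- buildHistogram(gf, bn = bn)
  sched <- computeSchedule(h, r1 = r1, step = step, rTh = rTh,
                           includeZero = includeZero)
  n <- length(sched@R)
  values <- matrix(0, nrow(gf@mag), ncol(gf@mag))
  if (gf@maxMag > 0) {
    for (i in seq_len(n)) {
      if (i > 1L && sched@s[i] == sched@s[i - 1L])
        next  # identical thresholds: no new pixels under first-layer priority
      e <- layerEdges(gf, sched@highTh[i], sched@lowTh[i])
      claim <- e & values == 0
      values[claim] <- 1 / i
    }
  }
  new("TextureImage", values = values, nLayers = as.integer(n),
      schedule = sched, id = id)
}
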