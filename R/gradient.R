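#' GradientHistogram: histogram of gradient magnitudes
#'
#' Equal-width bins partitioning \[0, M\] (M = maximum magnitude) in
#' ascending magnitude order; zero magnitudes fall in bin 1, so the counts
#' always sum to the pixel count.
#'
#' @slot counts numeric vector of per-bin pixel counts.
#' @slot bn integer number of bins.
#' @slot binWidth numeric, M/bn.
#' @slot total integer, total pixel count.
#' @export
setClass("GradientHistogram",
  representation(counts = "numeric", bn = "integer", binWidth = "numeric",
                 total = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != object@bn)
      msg <- c(msg, "counts must have bn entries")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (sum(object@counts) != object@total)
      msg <- c(msg, "counts must sum to the pixel total")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "GradientHistogram", function(object) {
  cat(sprintf("GradientHistogram: %d bins (width %.4g), %d pixels\n",
              object@bn, object@binWidth, object@total))
})

# shift a matrix by (dm, dn), padding with `fill`
shiftMat <- function(x, dm, dn, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dm):min(nr, nr + dm)
  cs <- max(1, 1 + dn):min(nc, nc + dn)
  out[rs, cs] <- x[rs - dm, cs - dn, drop = FALSE]
  out
}

gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

smooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  EBImage::imageData(EBImage::filter2(EBImage::Image(x),
                                      gaussKernel(sigma),
                                      boundary = "replicate"))
}

#' Compute the smoothed gradient field of a normalized image
#'
#' Gaussian smoothing at `sigma` followed by 3x3 Sobel derivatives; the
#' magnitude is the L2 norm of the two derivatives. Non-maximum
#' suppression along the quantized gradient direction is performed once
#' here and reused by every threshold layer.
#'
#' @param gi a [NormalizedImage-class] or a numeric matrix
#' @param sigma Gaussian smoothing sigma in pixels
#' @return a [GradientField-class]
#' @export
computeGradient <- function(gi, sigma = 1.4) {
  x <- if (is(gi, "NormalizedImage")) gi@gi else gi
  xs <- smooth2d(x, sigma)
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  gm <- EBImage::imageData(EBImage::filter2(EBImage::Image(xs), sob,
                                            boundary = "replicate"))
  gn <- EBImage::imageData(EBImage::filter2(EBImage::Image(xs), t(sob),
                                            boundary = "replicate"))
  mag <- sqrt(gm^2 + gn^2)

  # direction folded to [0, 180): sector 0 = gradient along columns,
  # 1 = down-right diagonal, 2 = along rows, 3 = down-left diagonal
  ang <- atan2(gm, gn)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(round(ang / (pi / 4))) %% 4L

  n1 <- matrix(0, nrow(mag), ncol(mag))
  n2 <- n1
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    d <- offs[[as.character(s)]]
    fwd <- shiftMat(mag, -d[1], -d[2])  # value at (m+dm, n+dn)
    bwd <- shiftMat(mag, d[1], d[2])
    n1[sel] <- fwd[sel]
    n2[sel] <- bwd[sel]
  }
  keep <- mag > 0 & mag >= n1 & mag >= n2
  nms <- mag * keep
  new("GradientField", mag = mag, nms = nms, maxMag = max(mag),
      sigma = sigma)
}

#' Histogram of gradient magnitudes
#'
#' @param gf a [GradientField-class]
#' @param bn number of bins (>= 2); the study value is 64
#' @return a [GradientHistogram-class]
#' @export
buildHistogram <- function(gf, bn = 64L) {
  stopifnot(bn >= 2)
  bn <- as.integer(bn)
  mag <- gf@mag
  M <- gf@maxMag
  if (M <= 0) {
    counts <- c(length(mag), rep(0, bn - 1L))
    return(new("GradientHistogram", counts = counts, bn = bn,
               binWidth = 0, total = length(mag)))
  }
  idx <- ceiling(mag / (M / bn))
  idx[idx < 1L] <- 1L
  idx[idx > bn] <- bn
  counts <- tabulate(idx, nbins = bn)
  new("GradientHistogram", counts = as.numeric(counts), bn = bn,
      binWidth = M / bn, total = length(mag))
}

#' Compute the descending hysteresis double-threshold schedule
#'
#' For each pixel-fraction R^i in (r1, r1 - step, ..., 0), the bin index
#' s^i is the smallest s whose ascending cumulative histogram count
#' reaches R^i times the pixel count; the layer's thresholds are then
#' highTh^i = s^i/Bn and lowTh^i = rTh * highTh^i (fractions of the
#' maximum gradient magnitude M). Because R decreases and cumulative
#' counts are monotone, highTh is non-increasing: the first layer uses the
#' strictest thresholds and extracts only the clearest textures.
#'
#' @param h a [GradientHistogram-class]
#' @param r1 first (largest) pixel fraction; study value 0.8
#' @param step decrement between consecutive fractions; study value 0.1
#' @param rTh low/high threshold ratio; study value 0.3
#' @param includeZero include the final R = 0 entry (for which s = 1)
#' @return a [ThresholdSchedule-class]
#' @export
computeSchedule <- function(h, r1 = 0.8, step = 0.1, rTh = 0.3,
                            includeZero = TRUE) {
  stopifnot(r1 > 0, r1 < 1, step > 0, rTh > 0, rTh < 1)
  k <- floor(r1 / step + 1e-9)
  R <- round(r1 - step * (0:k), 12)
  R[abs(R) < 1e-12] <- 0
  if (!includeZero) R <- R[R > 0]
  cs <- cumsum(h@counts)
  # ties at a bin boundary (cumulative count numerically equal to R*total)
  # resolve to the smaller bin
  s <- vapply(R, function(r) {
    target <- r * h@total
    which(cs >= target - 1e-6 * max(1, abs(target)))[1]
  }, integer(1))
  highTh <- s / h@bn
  new("ThresholdSchedule", R = R, s = as.integer(s), highTh = highTh,
      lowTh = rTh * highTh, bn = h@bn, rTh = rTh)
}

#' Edge map of one threshold layer
#'
#' Standard Canny edge generation on a precomputed gradient field:
#' non-maximum suppressed magnitudes thresholded with the hysteresis pair
#' (highTh * M, lowTh * M); weak pixels are kept only when 8-connected,
#' through other weak pixels, to a strong pixel.
#'
#' @param gf a [GradientField-class]
#' @param highTh,lowTh threshold fractions of the maximum magnitude M,
#'   with 0 <= lowTh <= highTh <= 1
#' @return logical edge matrix
#' @export
layerEdges <- function(gf, highTh, lowTh) {
  stopifnot(lowTh <= highTh, highTh <= 1, lowTh >= 0)
  M <- gf@maxMag
  if (M <= 0)
    return(matrix(FALSE, nrow(gf@mag), ncol(gf@mag)))
  strong <- gf@nms >= highTh * M & gf@nms > 0
  cand <- gf@nms >= lowTh * M & gf@nms > 0
  cpp_hysteresis(cand, strong & cand)
}
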