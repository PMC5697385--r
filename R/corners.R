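# Harris corner response on the MTI value grid, normalized to max 1.
# Returns every NMS-surviving candidate above `minResp` together with its
# response and importance value, so that corner sets at many thetas can be
# derived by thresholding without recomputing the response.
harrisCandidates <- function(mti, k = 0.04, windowSigma = 1.0,
                             nmsRadius = 1L, minResp = 0) {
  V <- mti@values
  empty <- data.frame(m = integer(0), n = integer(0),
                      response = numeric(0), importance = numeric(0))
  if (all(V == 0)) return(empty)

  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  gm <- EBImage::imageData(EBImage::filter2(EBImage::Image(V), sob,
                                            boundary = "replicate"))
  gn <- EBImage::imageData(EBImage::filter2(EBImage::Image(V), t(sob),
                                            boundary = "replicate"))
  A <- smooth2d(gm * gm, windowSigma)
  B <- smooth2d(gn * gn, windowSigma)
  Cc <- smooth2d(gm * gn, windowSigma)
  f <- A * B - Cc^2 - k * (A + B)^2
  fmax <- max(f)
  if (fmax <= 0) return(empty)
  f <- f / fmax

  # local maximum within a Chebyshev window of radius nmsRadius; ties are
  # broken by row-major priority (the earlier pixel wins)
  keep <- matrix(TRUE, nrow(f), ncol(f))
  for (dm in -nmsRadius:nmsRadius) {
    for (dn in -nmsRadius:nmsRadius) {
      if (dm == 0 && dn == 0) next
      nb <- shiftMat(f, dm, dn, fill = -Inf)
      earlier <- dm > 0 || (dm == 0 && dn > 0)  # neighbour precedes pixel
      keep <- keep & if (earlier) f > nb else f >= nb
    }
  }
  sel <- keep & V > 0 & f > minResp
  if (!any(sel)) return(empty)
  idx <- which(sel, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  data.frame(m = as.integer(idx[, 1]), n = as.integer(idx[, 2]),
             response = f[idx], importance = V[idx])
}

#' Detect importance-valued Harris corners on an MTI
#'
#' The Harris response F is computed on the MTI value grid (derivatives by
#' 3x3 Sobel, structure tensor smoothed with a Gaussian window, constant
#' k) and normalized by its maximum positive value so that the response
#' threshold theta is comparable across images. A pixel is a corner iff
#' its normalized response is at least theta, it is a local maximum within
#' `nmsRadius` (ties broken by row-major priority), and its MTI value is
#' positive. Each corner keeps the MTI value at its position as its
#' importance value.
#'
#' @param mti a [TextureImage-class]
#' @param theta corner response threshold in (0, 1\]; the study searched
#'   0.01..0.1 (CT) and 0.03..0.12 (MRI) in steps of 0.01
#' @param k Harris constant (classical value 0.04)
#' @param windowSigma Gaussian window sigma for the structure tensor
#' @param nmsRadius non-maximum suppression radius in pixels
#' @return a [CornerSet-class] (empty when the MTI is all background or
#'   the response has no positive maximum)
#' @export
detectCorners <- function(mti, theta = 0.04, k = 0.04, windowSigma = 1.0,
                          nmsRadius = 1L) {
  stopifnot(theta > 0, k > 0, k < 0.25)
  cand <- harrisCandidates(mti, k = k, windowSigma = windowSigma,
                           nmsRadius = nmsRadius)
  cand <- cand[cand$response >= theta, , drop = FALSE]
  newCornerSet(cbind(cand$m, cand$n), importance = cand$importance,
               response = cand$response, theta = theta, dim = dim(mti),
               id = mti@id)
}
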