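#' Extract the intracranial portion of a brain slice
#'
#' Brain slices consist of background, skull and the intracranial portion;
#' only the last carries diagnostic content. The sharp intensity step
#' between skull and brain tissue makes the skull boundary the strongest
#' edge structure, so the region is recovered from a Canny-style edge map:
#' the edge map is hole-filled, the largest enclosed interior region is
#' selected, and its contour-adjacent rim and any interior holes (e.g.
#' ventricle outlines) are re-filled so the mask is one solid 4-connected
#' region. When no closed contour encloses a usable region (e.g. an
#' already skull-stripped image with an open silhouette), the mask falls
#' back to the filled largest connected component of above-background
#' pixels.
#'
#' @param img a [BrainSlice-class]
#' @param cannySigma Gaussian smoothing sigma for the edge detector
#'   (pixels)
#' @param edgeR pixel fraction used to pick the high hysteresis threshold
#'   from the gradient histogram (see [computeSchedule()])
#' @param rTh low/high hysteresis threshold ratio
#' @return list with `image` (the slice with everything outside the mask
#'   zeroed) and `mask` (logical matrix)
#' @export
extractIntracranial <- function(img, cannySigma = 1.4, edgeR = 0.7,
                                rTh = 0.3) {
  x <- img@pixels
  if (max(x) <= 0)
    stop("no foreground: image is entirely background")

  gf <- computeGradient(x / (2^img@bitDepth - 1), sigma = cannySigma)
  mask <- NULL
  if (gf@maxMag > 0) {
    h <- buildHistogram(gf, bn = 64L)
    sched <- computeSchedule(h, r1 = edgeR, step = edgeR, rTh = rTh)
    edges <- layerEdges(gf, sched@highTh[1], sched@lowTh[1])
    mask <- enclosedRegion(edges, minArea = max(64, 0.005 * length(x)))
  }
  # fallback: filled largest above-background component — used when no
  # closed contour is found, or when the contour-derived region is
  # implausibly small against the visible foreground (broken contour)
  fg <- x > 0.02 * max(x)
  lab <- cpp_label8(fg)
  if (max(lab) == 0)
    stop("no foreground: image is entirely background")
  fgComp <- lab == which.max(tabulate(lab[lab > 0]))
  if (is.null(mask) || sum(mask) < 0.5 * sum(fgComp))
    mask <- EBImage::fillHull(fgComp * 1) > 0
  if (!any(mask))
    stop("no foreground: empty intracranial mask")
  x[!mask] <- 0
  list(image = new("BrainSlice", pixels = x, bitDepth = img@bitDepth,
                   id = img@id),
       mask = mask)
}

#' Rotate the intracranial portion into the vertical direction
#'
#' The orientation of the mask is estimated from its second central
#' moments: the angle between the principal axis and the (vertical) row
#' axis. Image and mask are rotated by the negative of that angle with
#' bilinear interpolation (nearest-neighbour for the mask). Near-circular
#' masks (principal axis ratio below `axisRatioMin`) are returned
#' unrotated with angle 0, since their orientation is not defined.
#'
#' @param img a [BrainSlice-class] (typically masked, from
#'   [extractIntracranial()])
#' @param mask logical matrix congruent with `img`
#' @param axisRatioMin minimum major/minor axis ratio for a defined
#'   orientation
#' @return list with `image`, `mask` and `angle` (degrees, the measured
#'   deviation from vertical)
#' @export
orientVertical <- function(img, mask, axisRatioMin = 1.05) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no foreground: empty mask")
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  cv <- crossprod(cc) / nrow(cc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 0 ||
      sqrt(eg$values[1] / eg$values[2]) < axisRatioMin)
    return(list(image = img, mask = mask, angle = 0))

  v <- eg$vectors[, 1]
  phi <- atan2(v[2], v[1]) * 180 / pi
  if (phi > 90) phi <- phi - 180
  if (phi <= -90) phi <- phi + 180

  maxv <- 2^img@bitDepth - 1
  rot <- EBImage::rotate(EBImage::Image(img@pixels), -phi,
                         filter = "bilinear", bg.col = 0)
  rot <- pmin(pmax(EBImage::imageData(rot), 0), maxv)
  rmask <- EBImage::rotate(EBImage::Image(mask * 1), -phi,
                           filter = "none", bg.col = 0)
  rmask <- EBImage::imageData(rmask) > 0.5
  rot[!rmask] <- 0
  list(image = new("BrainSlice", pixels = rot, bitDepth = img@bitDepth,
                   id = img@id),
       mask = rmask, angle = phi)
}

# Region enclosed by the strongest closed edge contour: among the edge
# components, pick the one enclosing the largest interior; when a nested
# contour (e.g. the inner skull boundary inside the outer one) itself
# encloses a comparably large interior, descend to it. Returns NULL when
# no contour encloses `minArea` pixels.
enclosedRegion <- function(edges, minArea, nestRatio = 0.5) {
  lab <- cpp_label8(edges)
  sizes <- tabulate(lab[lab > 0])
  cand <- which(sizes >= 30)
  if (!length(cand)) return(NULL)

  interiorOf <- function(k) {
    comp <- lab == k
    fill <- EBImage::fillHull(comp * 1) > 0
    list(fill = fill, interior = sum(fill) - sum(comp))
  }
  infos <- lapply(cand, interiorOf)
  areas <- vapply(infos, `[[`, numeric(1), "interior")
  if (max(areas) < minArea) return(NULL)

  best <- which.max(areas)
  fill <- infos[[best]]$fill
  area <- areas[best]
  repeat {
    inner <- which(vapply(seq_along(cand), function(i) {
      i != best && areas[i] >= nestRatio * area &&
        all(fill[lab == cand[i]])
    }, logical(1)))
    if (!length(inner)) break
    best <- inner[which.max(areas[inner])]
    fill <- infos[[best]]$fill
    area <- areas[best]
  }
  if (area < minArea) return(NULL)
  fill
}

# crop image and mask to the mask's axis-aligned bounding box
# (the "vertical external matrix")
cropToMask <- function(pixels, mask) {
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  px <- pixels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  mk <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  px[!mk] <- 0
  list(pixels = px, mask = mk)
}

#' Mean dimensions of a set of cropped slices
#'
#' The common normalization size (Row, Column) is the rounded mean of the
#' per-image cropped row and column counts, with round-half-up rounding.
#'
#' @param x an n-by-2 matrix of (rows, cols), or a list of matrices /
#'   [BrainSlice-class] objects whose dimensions are used
#' @return integer(2): (Row, Column)
#' @export
meanDims <- function(x) {
  if (is.list(x))
    x <- do.call(rbind, lapply(x, function(e) {
      if (is(e, "BrainSlice")) return(dim(e@pixels))
      if (is.matrix(e)) return(dim(e))
      e  # already a (rows, cols) pair
    }))
  x <- matrix(as.numeric(x), ncol = 2)
  if (nrow(x) == 0L)
    stop("meanDims: empty input")
  as.integer(floor(colMeans(x) + 0.5))
}

#' Normalize a brain slice to a common grid
#'
#' The full normalization chain: intracranial extraction, principal-axis
#' vertical orientation, crop to the mask bounding box, bilinear resize to
#' `target` = (Row, Column), and intensity rescaling to \[0,1\] by the
#' bit-depth maximum (so 8-bit CT and 16-bit MRI share one intensity
#' scale).
#'
#' @param img a [BrainSlice-class]
#' @param target integer(2) output (Row, Column); the default is the study
#'   size used for MRI slices
#' @param cannySigma,axisRatioMin see [extractIntracranial()] and
#'   [orientVertical()]
#' @return a [NormalizedImage-class]
#' @export
normalizeImage <- function(img, target = c(175L, 141L), cannySigma = 1.4,
                           axisRatioMin = 1.05) {
  stopifnot(length(target) == 2, all(target >= 32))
  ex <- extractIntracranial(img, cannySigma = cannySigma)
  ov <- orientVertical(ex$image, ex$mask, axisRatioMin = axisRatioMin)
  cp <- cropToMask(ov$image@pixels, ov$mask)
  resizeToNormalized(cp$pixels, target, img@bitDepth, img@id)
}

resizeToNormalized <- function(pixels, target, bitDepth, id) {
  rs <- EBImage::imageData(EBImage::resize(EBImage::Image(pixels),
                                           w = target[1], h = target[2]))
  gi <- pmin(pmax(rs / (2^bitDepth - 1), 0), 1)
  new("NormalizedImage", gi = gi, id = id)
}

#' Normalize a set of slices with a shared target size
#'
#' Each slice is extracted, oriented and cropped; if `targetDims` is NULL
#' the common size is then taken as [meanDims()] of the cropped slices,
#' mirroring how the study sizes (285 x 260 for CT, 175 x 141 for MRI)
#' were derived from their image sets.
#'
#' @param imgs list of [BrainSlice-class]
#' @param targetDims integer(2) or NULL for automatic mean dimensions
#' @param cannySigma,axisRatioMin see [normalizeImage()]
#' @return list of [NormalizedImage-class]; the common size is attached as
#'   attribute `targetDims`
#' @export
normalizeSet <- function(imgs, targetDims = NULL, cannySigma = 1.4,
                         axisRatioMin = 1.05) {
  stopifnot(length(imgs) > 0)
  cropped <- lapply(imgs, function(im) {
    ex <- extractIntracranial(im, cannySigma = cannySigma)
    ov <- orientVertical(ex$image, ex$mask, axisRatioMin = axisRatioMin)
    c(cropToMask(ov$image@pixels, ov$mask),
      list(bitDepth = im@bitDepth, id = im@id))
  })
  if (is.null(targetDims))
    targetDims <- meanDims(lapply(cropped, function(e) dim(e$pixels)))
  targetDims <- as.integer(targetDims)
  out <- lapply(cropped, function(e)
    resizeToNormalized(e$pixels, targetDims, e$bitDepth, e$id))
  attr(out, "targetDims") <- targetDims
  out
}
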