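#' Parameters of the synthetic brain phantom
#'
#' The phantom emulates the gross structure of an axial brain slice as a
#' classifier test-bed: a bright elliptical skull ring on zero background,
#' mid-intensity noisy intracranial tissue, two dark crescent-shaped
#' ventricle-like structures near the centre, and — for the "Abnormal"
#' class — one hypo- or hyperdense lesion blob in the tissue. Geometry
#' (orientation, axes, centre) is jittered per image. Intensities are
#' 8-bit and ordered background < ventricle < tissue < skull.
#'
#' @param rows,cols canvas size
#' @param skullIntensity,tissueIntensity,ventricleIntensity mean
#'   intensities (8-bit scale)
#' @param noiseSigma marginal standard deviation of the spatially
#'   correlated tissue noise field
#' @param lesionContrast absolute intensity offset of a lesion from the
#'   surrounding tissue
#' @param lesionRadius range (min, max) of lesion radii in pixels
#' @param maxRotation maximum absolute in-plane rotation (degrees)
#' @return parameter list
#' @export
phantomParams <- function(rows = 192L, cols = 192L, skullIntensity = 235,
                          tissueIntensity = 115, ventricleIntensity = 45,
                          noiseSigma = 8, lesionContrast = 60,
                          lesionRadius = c(9, 14), maxRotation = 15) {
  stopifnot(rows >= 64, cols >= 64,
            ventricleIntensity < tissueIntensity,
            tissueIntensity < skullIntensity)
  list(rows = as.integer(rows), cols = as.integer(cols),
       skullIntensity = skullIntensity, tissueIntensity = tissueIntensity,
       ventricleIntensity = ventricleIntensity, noiseSigma = noiseSigma,
       lesionContrast = lesionContrast, lesionRadius = lesionRadius,
       maxRotation = maxRotation)
}

# squared normalized ellipse radius of every pixel, in a frame rotated by
# alpha (radians) about (cm, cn)
ellipseR2 <- function(M, N, cm, cn, a, b, alpha) {
  u <- (M - cm) * cos(alpha) + (N - cn) * sin(alpha)
  v <- -(M - cm) * sin(alpha) + (N - cn) * cos(alpha)
  (u / a)^2 + (v / b)^2
}

#' Generate one synthetic brain phantom
#'
#' Deterministic given `seed`: the same seed reproduces the image
#' bit-for-bit. "Normal" phantoms are left/right symmetric up to noise;
#' "Abnormal" phantoms additionally carry one lesion blob whose side,
#' position, radius and polarity (hypo-/hyperdense) are drawn from the
#' seed.
#'
#' @param label "Normal" or "Abnormal"
#' @param seed integer seed
#' @param params see [phantomParams()]
#' @param details return ground-truth geometry alongside the image
#' @return a [BrainSlice-class]; with `details = TRUE`, a list with
#'   `image` and `meta` (centre, axes, rotation, lesion mask/polarity)
#' @export
makePhantom <- function(label = c("Normal", "Abnormal"), seed = 1L,
                        params = phantomParams(), details = FALSE) {
  label <- match.arg(label)
  p <- params
  withSeed(seed, {
    nr <- p$rows; nc <- p$cols
    M <- matrix(seq_len(nr), nr, nc)
    N <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    cm <- nr / 2 + stats::runif(1, -2, 2)
    cn <- nc / 2 + stats::runif(1, -2, 2)
    alpha <- stats::runif(1, -p$maxRotation, p$maxRotation) * pi / 180
    a <- 0.42 * nr * stats::runif(1, 0.92, 1)    # vertical semi-axis
    b <- 0.34 * nc * stats::runif(1, 0.92, 1)
    thick <- stats::runif(1, 5, 8)

    r2out <- ellipseR2(M, N, cm, cn, a, b, alpha)
    r2in <- ellipseR2(M, N, cm, cn, a - thick, b - thick, alpha)

    img <- matrix(0, nr, nc)
    skull <- r2out <= 1 & r2in > 1
    brain <- r2in <= 1
    # spatially correlated noise, as in reconstructed CT/MRI (iid pixel
    # noise would litter the texture layers with spurious corners)
    nz <- smooth2d(matrix(stats::rnorm(nr * nc), nr, nc), 1.2)
    nz <- nz * (p$noiseSigma / stats::sd(nz))
    img[skull] <- p$skullIntensity
    img[brain] <- p$tissueIntensity + nz[brain]

    # two mirrored crescent ventricles: ellipse minus a laterally shifted
    # copy, placed either side of the (rotated) midline; abnormal slices
    # show mass effect — one ventricle asymmetrically enlarged
    voff <- stats::runif(1, 0.10, 0.14) * b
    va <- 0.30 * a; vb <- 0.10 * b
    vscale <- c(1, 1)
    if (label == "Abnormal") {
      enlarged <- sample(1:2, 1)
      vscale[enlarged] <- stats::runif(1, 1.4, 1.7)
    }
    for (side in c(-1, 1)) {
      sc <- vscale[(side + 3) / 2]
      vcm <- cm - side * voff * sin(alpha)
      vcn <- cn + side * voff * cos(alpha)
      outer2 <- ellipseR2(M, N, vcm, vcn, sc * va, sc * vb, alpha)
      bite <- ellipseR2(M, N,
                        vcm - side * 0.5 * sc * vb * sin(alpha),
                        vcn + side * 0.5 * sc * vb * cos(alpha),
                        sc * va, sc * vb, alpha)
      vmask <- outer2 <= 1 & bite > 1 & brain
      img[vmask] <- p$ventricleIntensity + nz[vmask] / 2
    }

    lmask <- NULL
    polarity <- NA_integer_
    if (label == "Abnormal") {
      side <- sample(c(-1, 1), 1)
      rad <- stats::runif(1, p$lesionRadius[1], p$lesionRadius[2])
      lm <- cm + stats::runif(1, -0.45, 0.45) * a * cos(alpha)
      ln <- cn + side * stats::runif(1, 0.35, 0.55) * b
      lmask <- (M - lm)^2 + (N - ln)^2 <= rad^2
      lmask <- lmask & ellipseR2(M, N, cm, cn, a - thick - 3,
                                 b - thick - 3, alpha) <= 1
      polarity <- sample(c(-1, 1), 1)
      img[lmask] <- p$tissueIntensity + polarity * p$lesionContrast +
        nz[lmask] / 2
    }

    img <- round(pmin(pmax(img, 0), 255))
    slice <- new("BrainSlice", pixels = img, bitDepth = 8L,
                 id = sprintf("phantom_%s_%d", tolower(label), seed))
    if (!details) return(slice)
    list(image = slice,
         meta = list(center = c(cm, cn), axes = c(a, b), thick = thick,
                     alpha = alpha, brain = brain, lesion = lmask,
                     polarity = polarity))
  })
}

#' Generate a labeled phantom dataset
#'
#' A seeded list of phantoms with per-image sub-seeds drawn from `seed`,
#' `nNormal` of class "Normal" followed by `nAbnormal` of class
#' "Abnormal".
#'
#' @param nNormal,nAbnormal class sizes (>= 0)
#' @param seed integer master seed
#' @param params see [phantomParams()]
#' @return list with elements `images` (list of [BrainSlice-class]) and
#'   `labels` (character vector)
#' @export
makeDataset <- function(nNormal, nAbnormal, seed = 17L,
                        params = phantomParams()) {
  stopifnot(nNormal >= 0, nAbnormal >= 0)
  n <- nNormal + nAbnormal
  labels <- rep(c("Normal", "Abnormal"), c(nNormal, nAbnormal))
  if (n == 0L)
    return(list(images = list(), labels = character(0)))
  subSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  images <- lapply(seq_len(n), function(i)
    makePhantom(labels[i], seed = subSeeds[i], params = params))
  list(images = images, labels = labels)
}
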