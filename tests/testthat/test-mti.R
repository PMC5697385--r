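test_that("gradient of a constant image is identically zero", {
  gf <- computeGradient(matrix(0.5, 30, 30))
  expect_true(all(gf@mag == 0))
  expect_identical(gf@maxMag, 0)
})

test_that("step-edge gradients are translation-symmetric and linear in height", {
  step <- function(h) {
    x <- matrix(0, 40, 40); x[, 21:40] <- h; x
  }
  gf <- computeGradient(step(0.8))
  peak <- apply(gf@mag[10:30, ], 1, max)
  expect_lt(diff(range(peak)) / mean(peak), 1e-6)  # equal along the edge
  gf2 <- computeGradient(step(0.4))
  expect_lt(abs(gf@maxMag / gf2@maxMag - 2), 0.02) # 2:1 within 1%
})

test_that("histogram partitions [0, M] and conserves the pixel count", {
  mkGF <- function(mag) new("GradientField", mag = mag,
                            nms = mag, maxMag = max(mag), sigma = 0)
  zero <- mkGF(matrix(0, 5, 4))
  h0 <- buildHistogram(zero, bn = 8L)
  expect_identical(h0@counts, c(20, rep(0, 7)))

  four <- mkGF(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2))
  h4 <- buildHistogram(four, bn = 4L)
  expect_identical(h4@counts, rep(1, 4))

  set.seed(11)
  for (i in 1:5) {
    mag <- matrix(stats::rexp(600), 20, 30)
    h <- buildHistogram(mkGF(mag), bn = 64L)
    expect_identical(sum(h@counts), 600)
  }
})

test_that("the schedule follows the cumulative-histogram rule", {
  h <- new("GradientHistogram", counts = c(10, 20, 30, 40), bn = 4L,
           binWidth = 0.1, total = 100L)
  sc <- computeSchedule(h, r1 = 0.8, step = 0.1, rTh = 0.3)
  expect_equal(sc@R, seq(0.8, 0, by = -0.1))
  # cumsum = 10, 30, 60, 100
  expect_identical(sc@s, c(4L, 4L, 3L, 3L, 3L, 2L, 2L, 1L, 1L))
  expect_equal(sc@highTh[1], 1.0)
  expect_equal(sc@highTh[sc@R == 0.5], 0.75)
  expect_equal(sc@highTh[sc@R == 0.1], 0.25)
  expect_equal(sc@lowTh / sc@highTh, rep(0.3, 9))

  # degenerate: everything in bin 1
  h1 <- new("GradientHistogram", counts = c(50, 0, 0, 0), bn = 4L,
            binWidth = 0, total = 50L)
  sc1 <- computeSchedule(h1)
  expect_true(all(sc1@s == 1L))
  expect_true(all(sc1@highTh == 1 / 4))
})

test_that("schedule satisfies the minimal-cumulative property on random histograms", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- as.numeric(rmultinom(1, size = 5000, prob = runif(64)))
    h <- new("GradientHistogram", counts = counts, bn = 64L,
             binWidth = 1, total = 5000L)
    sc <- computeSchedule(h)
    cs <- cumsum(counts)
    for (i in seq_along(sc@R)) {
      s <- sc@s[i]
      expect_gte(cs[s], sc@R[i] * 5000 - 1e-6)
      if (s > 1L) expect_lt(cs[s - 1L], sc@R[i] * 5000 + 1e-6)
    }
    expect_true(all(diff(sc@highTh) <= 0))
  }
})

test_that("layer edges: empty on flat fields, monotone in thresholds, thin on a step", {
  flat <- computeGradient(matrix(0.3, 30, 30))
  expect_false(any(layerEdges(flat, 0.5, 0.15)))

  set.seed(21)
  x <- randomToyImage()
  gf <- computeGradient(x)
  eHigh <- layerEdges(gf, 0.9, 0.27)
  eLow <- layerEdges(gf, 0.3, 0.09)
  expect_true(all(eLow[eHigh]))  # stricter edges are a subset

  step <- matrix(0, 40, 40); step[, 21:40] <- 0.8
  gfs <- computeGradient(step)
  e <- layerEdges(gfs, 0.5, 0.15)
  inner <- e[8:32, ]
  expect_true(all(rowSums(inner) == 1))            # one pixel per row
  expect_true(all(which(colSums(inner) > 0) %in% 19:22))  # at the step
})

test_that("MTI values are 1/layer with first-layer priority", {
  expect_true(all(mtiValues(buildMTI(matrix(0.4, 40, 40))) == 0))

  set.seed(33)
  for (rep in 1:4) {
    x <- randomToyImage()
    mti <- buildMTI(x)
    v <- mtiValues(mti)
    nz <- v[v != 0]
    expect_true(all(abs(nz - 1 / round(1 / nz)) < 1e-12))
    expect_true(all(round(1 / nz) >= 1 & round(1 / nz) <= nLayers(mti)))

    # recompute the per-layer maps independently and check the claimed layer
    gf <- computeGradient(x)
    sc <- computeSchedule(buildHistogram(gf))
    maps <- lapply(seq_along(sc@R), function(i)
      layerEdges(gf, sc@highTh[i], sc@lowTh[i]))
    idx <- which(v != 0, arr.ind = TRUE)
    layer <- round(1 / v[idx])
    for (k in seq_len(nrow(idx))) {
      i <- layer[k]
      expect_true(maps[[i]][idx[k, 1], idx[k, 2]])
      if (i > 1L)
        expect_false(any(vapply(seq_len(i - 1L), function(j)
          maps[[j]][idx[k, 1], idx[k, 2]], logical(1))))
    }
    # background pixels belong to no layer
    bg <- which(v == 0)
    anyLayer <- Reduce(`|`, maps)
    expect_false(any(anyLayer[bg]))
  }
})

test_that("MTI is invariant under global intensity rescaling", {
  set.seed(44)
  x <- randomToyImage()
  ref <- mtiValues(buildMTI(x))
  expect_identical(mtiValues(buildMTI(x * 0.5)), ref)
  expect_identical(mtiValues(buildMTI(x * 0.25)), ref)
})

test_that("a weak edge isolated from strong texture falls into a later layer", {
  # high-contrast stripes fill the upper histogram bins; a faint step,
  # separated from them by a flat gap (no hysteresis path), must be
  # claimed by a later, laxer layer
  x <- matrix(0.5, 48, 48)
  stripe <- rep(rep(c(0.3, 0.7), each = 3), length.out = 24)
  x[, 1:24] <- matrix(stripe, 48, 24, byrow = TRUE)
  x[, 41:48] <- 0.5 + 0.032
  v <- mtiValues(buildMTI(x))
  stripeRegion <- v[, 1:25]
  expect_true(any(stripeRegion == 1))          # clearest edges in layer 1
  weakRegion <- v[, 39:43]
  weakVals <- weakRegion[weakRegion != 0]
  expect_gt(length(weakVals), 0)               # the faint step is extracted
  expect_true(all(weakVals <= 1 / 2))          # but never into layer 1
})
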