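# a clean unrotated skull-ring image with analytically known interior
ringImage <- function(rows = 120L, cols = 120L, a = 50, b = 38, thick = 6,
                      skull = 240, tissue = 120) {
  M <- matrix(seq_len(rows), rows, cols)
  N <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  cm <- rows / 2; cn <- cols / 2
  r2o <- ((M - cm) / a)^2 + ((N - cn) / b)^2
  r2i <- ((M - cm) / (a - thick))^2 + ((N - cn) / (b - thick))^2
  img <- matrix(0, rows, cols)
  img[r2o <= 1] <- skull
  img[r2i <= 1] <- tissue
  list(img = new("BrainSlice", pixels = img, bitDepth = 8L, id = "ring"),
       interior = r2i <= 1,
       innerAxes = c(a - thick, b - thick), center = c(cm, cn))
}

test_that("intracranial mask recovers the skull interior within 2 px", {
  rg <- ringImage()
  ex <- extractIntracranial(rg$img)
  M <- matrix(seq_len(120), 120, 120)
  N <- matrix(seq_len(120), 120, 120, byrow = TRUE)
  shrink <- ((M - rg$center[1]) / (rg$innerAxes[1] - 2))^2 +
    ((N - rg$center[2]) / (rg$innerAxes[2] - 2))^2 <= 1
  grow <- ((M - rg$center[1]) / (rg$innerAxes[1] + 2))^2 +
    ((N - rg$center[2]) / (rg$innerAxes[2] + 2))^2 <= 1
  expect_true(all(ex$mask[shrink]))      # mask covers interior minus 2 px
  expect_false(any(ex$mask[!grow]))      # mask within interior plus 2 px
  expect_true(all(ex$image@pixels[!ex$mask] == 0))
})

test_that("an entirely background image signals no foreground", {
  blank <- new("BrainSlice", pixels = matrix(0, 40, 40), bitDepth = 8L,
               id = "blank")
  expect_error(extractIntracranial(blank), "no foreground")
})

test_that("a pre-stripped image keeps its own support as the mask", {
  M <- matrix(seq_len(80), 80, 80)
  N <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  support <- ((M - 40) / 28)^2 + ((N - 40) / 22)^2 <= 1
  img <- matrix(0, 80, 80)
  img[support] <- 130
  ex <- extractIntracranial(new("BrainSlice", pixels = img, bitDepth = 8L,
                                id = "stripped"))
  iou <- sum(ex$mask & support) / sum(ex$mask | support)
  expect_gt(iou, 0.95)
})

rotEllipseMask <- function(rows, cols, a, b, angleDeg) {
  M <- matrix(seq_len(rows), rows, cols)
  N <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  al <- angleDeg * pi / 180
  cm <- rows / 2; cn <- cols / 2
  u <- (M - cm) * cos(al) + (N - cn) * sin(al)
  v <- -(M - cm) * sin(al) + (N - cn) * cos(al)
  (u / a)^2 + (v / b)^2 <= 1
}

test_that("orientation recovers a 30-degree tilt and converges", {
  mask <- rotEllipseMask(140, 140, 55, 30, 30)
  img <- new("BrainSlice", pixels = mask * 180, bitDepth = 8L, id = "e30")
  ov <- orientVertical(img, mask)
  expect_lt(abs(ov$angle - 30), 1)
  ov2 <- orientVertical(ov$image, ov$mask)
  expect_lt(abs(ov2$angle), 1)
})

test_that("already-vertical and circular masks are left unrotated", {
  maskV <- rotEllipseMask(120, 120, 50, 28, 0)
  imgV <- new("BrainSlice", pixels = maskV * 180, bitDepth = 8L, id = "v")
  ovV <- orientVertical(imgV, maskV)
  expect_lt(abs(ovV$angle), 1)

  maskC <- rotEllipseMask(100, 100, 35, 35, 0)
  imgC <- new("BrainSlice", pixels = maskC * 180, bitDepth = 8L, id = "c")
  ovC <- orientVertical(imgC, maskC)
  expect_identical(ovC$angle, 0)
  expect_identical(ovC$image@pixels, imgC@pixels)
})

test_that("meanDims is the round-half-up mean of cropped dimensions", {
  expect_identical(meanDims(rbind(c(280, 260), c(290, 260))),
                   c(285L, 260L))
  expect_identical(meanDims(rbind(c(100, 90))), c(100L, 90L))
  expect_identical(meanDims(rbind(c(101, 90), c(102, 90))), c(102L, 90L))
  expect_error(meanDims(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("normalization yields exact target dims, [0,1] range, no empty border", {
  ph <- makePhantom("Normal", seed = 5)
  ni <- normalizeImage(ph, target = c(175L, 141L))
  expect_identical(dim(ni), c(175L, 141L))
  gi <- mtiValues(buildMTI(ni))  # also exercises downstream compatibility
  expect_true(all(ni@gi >= 0 & ni@gi <= 1))

  # crop removes the zero margin entirely before resizing
  ex <- extractIntracranial(ph)
  ov <- orientVertical(ex$image, ex$mask)
  cp <- CornerDx:::cropToMask(ov$image@pixels, ov$mask)
  expect_gt(sum(cp$pixels[1, ] + cp$pixels[nrow(cp$pixels), ]), 0)
  expect_gt(sum(cp$mask[, 1]) + sum(cp$mask[, ncol(cp$mask)]), 0)
})

test_that("normalization is near-idempotent on already-normalized input", {
  ph <- makePhantom("Normal", seed = 9)
  ni <- normalizeImage(ph, target = c(160L, 136L))
  again <- new("BrainSlice", pixels = round(ni@gi * 255), bitDepth = 8L,
               id = "again")
  ni2 <- normalizeImage(again, target = c(160L, 136L))
  expect_identical(dim(ni2), dim(ni))
  expect_lt(mean(abs(ni2@gi - ni@gi)), 0.02)
})
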