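test_that("knn voting follows similarity order with deterministic ties", {
  labels <- c("Normal", "Abnormal", "Abnormal", "Normal")
  expect_identical(CornerDx:::knnVote(c(0.9, 0.5, 0.4, 0.1), labels, 1L),
                   "Normal")
  # k = 3: two Abnormal beat one Normal
  expect_identical(CornerDx:::knnVote(c(0.9, 0.8, 0.7, 0.1), labels, 3L),
                   "Abnormal")
  # tied 1-1 vote: the most similar neighbour decides
  expect_identical(CornerDx:::knnVote(c(0.9, 0.8, 0.1, 0.1), labels, 2L),
                   "Normal")
  # tied similarities resolve to the smaller training index
  expect_identical(CornerDx:::knnVote(c(0.5, 0.5, 0.1, 0.1), labels, 1L),
                   "Normal")
  # unanimity regardless of similarity
  expect_identical(CornerDx:::knnVote(c(0, 0, 0), rep("Abnormal", 3), 3L),
                   "Abnormal")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  labels <- rep(c("Normal", "Abnormal"), c(12, 8))
  f1 <- CornerDx:::stratifiedFolds(labels, 4L, seed = 3L)
  f2 <- CornerDx:::stratifiedFolds(labels, 4L, seed = 3L)
  expect_identical(f1, f2)
  expect_true(all(tabulate(f1, 4) == 5))
  for (k in 1:4) {
    expect_identical(sum(labels[f1 == k] == "Normal"), 3L)
    expect_identical(sum(labels[f1 == k] == "Abnormal"), 2L)
  }
  expect_false(identical(f1, CornerDx:::stratifiedFolds(labels, 4L, 4L)))
})

smallPhantomMTIs <- function(nPerClass, seed, dims = c(120L, 104L)) {
  ds <- makeDataset(nPerClass, nPerClass, seed = seed,
                    params = phantomParams(rows = 144L, cols = 144L))
  nis <- normalizeSet(ds$images, targetDims = dims)
  list(mtis = lapply(nis, buildMTI), labels = ds$labels)
}

test_that("cross-validation bookkeeping: singleton grid, sane accuracies", {
  d <- smallPhantomMTIs(4, seed = 101)
  cv <- crossValidate(d$mtis, d$labels, thetaGrid = 0.04, kGrid = 3L,
                      folds = 2L, seed = 1L)
  expect_identical(cv$thetaC, 0.04)
  expect_identical(cv$kC, 3L)
  expect_identical(nrow(cv$grid), 1L)
  expect_true(all(cv$grid$accuracy >= 0 & cv$grid$accuracy <= 1))
  expect_error(crossValidate(d$mtis, rep("Normal", 8), thetaGrid = 0.04,
                             kGrid = 3L),
               "both classes")
})

test_that("selection avoids a degenerate theta that kills the corners", {
  ds <- makeDataset(10, 10, seed = 102)
  nis <- normalizeSet(ds$images)
  mtis <- lapply(nis, buildMTI)
  cv <- crossValidate(mtis, ds$labels, thetaGrid = c(0.04, 0.995),
                      kGrid = 3L, folds = 5L, seed = 2L)
  expect_identical(cv$thetaC, 0.04)
  accs <- cv$grid$accuracy
  expect_gt(accs[cv$grid$theta == 0.04], accs[cv$grid$theta == 0.995])
})

test_that("a trained classifier predicts held-out phantoms end to end", {
  d <- smallPhantomMTIs(6, seed = 103)
  clf <- trainClassifier(d$mtis, d$labels, thetaGrid = c(0.02, 0.04),
                         kGrid = c(3L, 5L), folds = 3L, seed = 5L,
                         targetDims = c(120L, 104L))
  expect_s4_class(clf, "CornerClassifier")
  expect_true(clf@thetaC %in% c(0.02, 0.04))
  expect_true(clf@kC %in% c(3L, 5L))

  held <- smallPhantomMTIs(2, seed = 104)
  pred <- vapply(held$mtis, function(m) predictLabel(clf, m), character(1))
  expect_true(all(pred %in% c("Normal", "Abnormal")))
  # prediction is deterministic
  pred2 <- vapply(held$mtis, function(m) predictLabel(clf, m), character(1))
  expect_identical(pred, pred2)
})

test_that("classification metrics follow the standard confusion formulas", {
  truth <- c("Normal", "Normal", "Normal", "Abnormal", "Abnormal")
  pred <- c("Normal", "Normal", "Abnormal", "Normal", "Abnormal")
  m <- classificationMetrics(truth, pred)
  expect_equal(m[["accuracy"]], 3 / 5)
  expect_equal(m[["precision"]], 2 / 3)
  expect_equal(m[["recall"]], 2 / 3)
  expect_equal(m[["f1"]], 2 / 3)
})
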