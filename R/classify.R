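#' KNN prediction from similarities
#'
#' Ranks the training items by similarity to the test corner set (ties in
#' similarity broken by the smaller training index), takes the kC most
#' similar, and returns the majority label; a tied vote is broken by the
#' label of the single most similar neighbour.
#'
#' @param test a [CornerSet-class]
#' @param clf a trained [CornerClassifier-class]
#' @return character label
#' @export
knnPredict <- function(test, clf) {
  if (length(clf@training) == 0L)
    stop("empty training set")
  sims <- vapply(clf@training, function(tr)
    imageSimilarity(test, tr, clf@simParams), numeric(1))
  knnVote(sims, clf@labels, clf@kC)
}

# majority vote among the k most similar; deterministic tie rules
knnVote <- function(sims, labels, k) {
  o <- order(-sims, seq_along(sims))
  top <- labels[o[seq_len(min(k, length(sims)))]]
  tab <- table(top)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L) top[1] else best
}

#' Stratified cross-validation over the (theta, K) grid
#'
#' Splits the images into `folds` stratified folds (seeded shuffle within
#' each class). For every theta in `thetaGrid`, corners are (re)derived at
#' that threshold and all pairwise similarities computed; for every K in
#' `kGrid`, each image is predicted from the training images outside its
#' fold and the mean validation accuracy recorded. The returned (thetaC,
#' kC) maximizes accuracy, with ties resolved toward smaller K, then
#' smaller theta.
#'
#' @param mtis list of [TextureImage-class]
#' @param labels character vector of "Normal"/"Abnormal"
#' @param thetaGrid corner-response thresholds to search; default is the
#'   CT study grid 0.01..0.1 step 0.01
#' @param kGrid neighbour counts to search; default 3..21 step 2
#' @param folds number of folds (study value 5)
#' @param seed seed for the stratified shuffle
#' @param params similarity parameters, see [simParams()]
#' @param harris list of Harris parameters passed to [detectCorners()]
#' @return list with `thetaC`, `kC`, `grid` (data.frame theta, k,
#'   accuracy), `foldId`, `seed`
#' @export
crossValidate <- function(mtis, labels, thetaGrid = seq(0.01, 0.1, by = 0.01),
                          kGrid = seq(3L, 21L, by = 2L), folds = 5L,
                          seed = 17L, params = simParams(),
                          harris = list(k = 0.04, windowSigma = 1.0,
                                        nmsRadius = 1L)) {
  stopifnot(length(mtis) == length(labels), folds >= 2,
            length(thetaGrid) > 0, length(kGrid) > 0)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("cross-validation requires both classes to be present")

  foldId <- stratifiedFolds(labels, folds, seed)
  cand <- lapply(mtis, function(m)
    harrisCandidates(m, k = harris$k, windowSigma = harris$windowSigma,
                     nmsRadius = harris$nmsRadius))

  grid <- expand.grid(theta = thetaGrid, k = as.integer(kGrid))
  grid$accuracy <- NA_real_
  n <- length(mtis)
  for (th in thetaGrid) {
    sets <- lapply(seq_along(mtis), function(i) {
      ci <- cand[[i]]
      ci <- ci[ci$response >= th, , drop = FALSE]
      newCornerSet(cbind(ci$m, ci$n), importance = ci$importance,
                   response = ci$response, theta = th,
                   dim = dim(mtis[[i]]), id = mtis[[i]]@id)
    })
    S <- pairwiseSimilarity(sets, params)
    for (k in kGrid) {
      pred <- vapply(seq_len(n), function(i) {
        train <- which(foldId != foldId[i])
        knnVote(S[i, train], labels[train], k)
      }, character(1))
      grid$accuracy[grid$theta == th & grid$k == k] <- mean(pred == labels)
    }
  }
  best <- grid[order(-grid$accuracy, grid$k, grid$theta), ][1, ]
  list(thetaC = best$theta, kC = as.integer(best$k), grid = grid,
       foldId = foldId, seed = seed)
}

# seeded stratified fold assignment
stratifiedFolds <- function(labels, folds, seed) {
  foldId <- integer(length(labels))
  rs <- withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]  # safe for singleton classes
      foldId[idx] <- rep_len(seq_len(folds), length(idx))
    }
    foldId
  })
  rs
}

# evaluate an expression with a local RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Train a corner-based classifier
#'
#' Runs [crossValidate()] to select (thetaC, kC), then stores the corner
#' sets of all images detected at thetaC together with their labels as the
#' classifier.
#'
#' @inheritParams crossValidate
#' @param targetDims the normalization size the training images share
#'   (recorded so raw test slices can be normalized identically)
#' @return a [CornerClassifier-class]
#' @export
trainClassifier <- function(mtis, labels, thetaGrid = seq(0.01, 0.1, by = 0.01),
                            kGrid = seq(3L, 21L, by = 2L), folds = 5L,
                            seed = 17L, params = simParams(),
                            targetDims = dim(mtis[[1]]),
                            harris = list(k = 0.04, windowSigma = 1.0,
                                          nmsRadius = 1L)) {
  cv <- crossValidate(mtis, labels, thetaGrid = thetaGrid, kGrid = kGrid,
                      folds = folds, seed = seed, params = params,
                      harris = harris)
  training <- lapply(mtis, detectCorners, theta = cv$thetaC, k = harris$k,
                     windowSigma = harris$windowSigma,
                     nmsRadius = harris$nmsRadius)
  new("CornerClassifier", training = training,
      labels = as.character(labels), thetaC = cv$thetaC, kC = cv$kC,
      simParams = params, targetDims = as.integer(targetDims),
      cvGrid = cv$grid)
}

#' @rdname predictLabel
setMethod("predictLabel", signature("CornerClassifier", "CornerSet"),
  function(object, newdata, ...) knnPredict(newdata, object))

#' @rdname predictLabel
setMethod("predictLabel", signature("CornerClassifier", "TextureImage"),
  function(object, newdata, ...)
    knnPredict(detectCorners(newdata, theta = object@thetaC), object))

#' @rdname predictLabel
setMethod("predictLabel", signature("CornerClassifier", "NormalizedImage"),
  function(object, newdata, ...)
    predictLabel(object, buildMTI(newdata)))

#' @rdname predictLabel
setMethod("predictLabel", signature("CornerClassifier", "BrainSlice"),
  function(object, newdata, ...)
    predictLabel(object, normalizeImage(newdata,
                                        target = object@targetDims)))

#' Two-class classification metrics
#'
#' Accuracy, precision, recall and F1, treating `positive` ("Normal", as
#' in the study) as the positive class.
#'
#' @param truth,pred character vectors of true and predicted labels
#' @param positive the positive class label
#' @return named numeric vector
#' @export
classificationMetrics <- function(truth, pred, positive = "Normal") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0)
    2 * precision * recall / (precision + recall) else NaN
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1)
}
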