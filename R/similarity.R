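#' Similarity parameters
#'
#' Controls the image-similarity function. `wMode` selects how the
#' unmatched-count weight W handles its two degenerate branches:
#' \describe{
#'   \item{"as_printed"}{the literal piecewise form: W = 0 when
#'     |C| = |C'|, the cap when the count difference is 1 (where log 1 = 0
#'     would divide by zero), else 1/log(d). The zero branch makes an
#'     image maximally dissimilar to itself — kept for fidelity
#'     experiments.}
#'   \item{"guarded"}{(default) W = cap for count differences of 0 or 1,
#'     else 1/log(d) — monotone non-increasing in the count difference and
#'     maximal when the two images have (nearly) equal corner counts,
#'     consistent with the intent that few unmatched corners mean high
#'     similarity.}
#' }
#'
#' @param wMode "guarded" or "as_printed"
#' @param epsilon distance floor (pixels) for the matched degree, so a
#'   zero-distance pair has finite degree 1/epsilon
#' @param logBase base of the logarithm in W
#' @param wCap weight used at the degenerate branches; defaults to
#'   1/log(2) in the chosen base
#' @return a list of class parameters
#' @export
simParams <- function(wMode = c("guarded", "as_printed"), epsilon = 0.5,
                      logBase = exp(1), wCap = 1 / log(2, base = logBase)) {
  stopifnot(epsilon > 0, wCap > 0, logBase > 1)
  list(wMode = match.arg(wMode), epsilon = epsilon, logBase = logBase,
       wCap = wCap)
}

#' Matched degree of a corner pair
#'
#' The contribution of one matched pair to the similarity: the reciprocal
#' of its distance, floored at `epsilon` so coincident corners contribute
#' a finite 1/epsilon.
#'
#' @param dis Euclidean distance(s) in pixels
#' @param params see [simParams()]
#' @return numeric, strictly decreasing in `dis` for dis >= epsilon
#' @export
matchedDegree <- function(dis, params = simParams()) {
  1 / pmax(dis, params$epsilon)
}

#' Unmatched-count weight W
#'
#' Depends only on the corner-count difference d = ||C| - |C'||, since the
#' matched pairs cancel: (|C| - |CM|) - (|C'| - |CM|) = |C| - |C'|.
#'
#' @param nC,nC2 corner counts of the two images
#' @param params see [simParams()]
#' @return non-negative weight
#' @export
countWeight <- function(nC, nC2, params = simParams()) {
  stopifnot(nC >= 0, nC2 >= 0)
  d <- abs(nC - nC2)
  if (params$wMode == "as_printed") {
    if (d == 0) return(0)
    if (d == 1) return(params$wCap)
    return(1 / log(d, base = params$logBase))
  }
  if (d <= 1) params$wCap else 1 / log(d, base = params$logBase)
}

#' Similarity of two corner-represented images
#'
#' SIM = W(|C|, |C'|) times the sum of matched degrees over the final
#' matched corner pair sequence. Zero when no pair matches.
#'
#' @param left,right [CornerSet-class] objects
#' @param params see [simParams()]
#' @return non-negative similarity
#' @export
imageSimilarity <- function(left, right, params = simParams()) {
  cm <- matchCorners(left, right)
  countWeight(cm@nLeft, cm@nRight, params) *
    sum(matchedDegree(cm@pairs$dis, params))
}

# lower-triangle pairwise similarity matrix over a list of corner sets
pairwiseSimilarity <- function(sets, params = simParams()) {
  n <- length(sets)
  S <- matrix(0, n, n)
  if (n < 2) return(S)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- imageSimilarity(sets[[i]], sets[[j]], params)
    }
  }
  S
}
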