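#' Are two corners a matched corner pair?
#'
#' Two corners from different images match when their Euclidean distance
#' does not exceed the sum of their mobilities (reciprocal importance
#' values): important corners are allowed little positional slack,
#' unimportant ones more.
#'
#' @param m,n,importance position and importance of the first corner
#' @param m2,n2,importance2 position and importance of the second corner
#' @return logical
#' @export
isMatch <- function(m, n, importance, m2, n2, importance2) {
  d <- sqrt((m - m2)^2 + (n - n2)^2)
  d <= mobility(importance) + mobility(importance2)
}

#' Initial matched corner pair sequence
#'
#' All pairs (c, c') with c from `left`, c' from `right` whose distance is
#' within the sum of the two mobilities; possibly one-to-many. Pairs are
#' ordered by left corner (row-major corner order), then right corner.
#'
#' @param left,right [CornerSet-class] objects
#' @return data.frame with columns `left`, `right` (corner indices) and
#'   `dis` (Euclidean pixel distance)
#' @export
initialMatches <- function(left, right) {
  nl <- nCorners(left); nr <- nCorners(right)
  if (nl == 0L || nr == 0L)
    return(data.frame(left = integer(0), right = integer(0),
                      dis = numeric(0)))
  D <- sqrt(outer(left@coords[, 1], right@coords[, 1], "-")^2 +
            outer(left@coords[, 2], right@coords[, 2], "-")^2)
  reach <- outer(mobility(left), mobility(right), "+")
  hit <- which(D <= reach, arr.ind = TRUE)
  o <- order(hit[, 1], hit[, 2])
  hit <- hit[o, , drop = FALSE]
  data.frame(left = as.integer(hit[, 1]), right = as.integer(hit[, 2]),
             dis = D[hit])
}

#' Final matched corner pair sequence
#'
#' Resolves the (possibly one-to-many) initial candidate list into a
#' one-to-one matching of maximum cardinality and, among all
#' maximum-cardinality matchings, minimum total distance — the assignment
#' problem on the bipartite candidate graph, solved by the Hungarian
#' method on a square cost matrix where non-candidate cells carry
#' BIG = 1 + sum of all candidate distances (so cardinality strictly
#' dominates cost). Ties between equal-cost optima are resolved
#' deterministically in favour of lower corner indices.
#'
#' @param ci candidate data.frame from [initialMatches()]
#' @param nLeft,nRight the full corner counts |C| and |C'| (stored for the
#'   similarity weight; corners absent from every candidate pair stay
#'   unmatched but still count here)
#' @return a [CornerMatching-class]
#' @export
finalMatches <- function(ci, nLeft = max(ci$left, 0L),
                         nRight = max(ci$right, 0L)) {
  emptyPairs <- data.frame(left = integer(0), right = integer(0),
                           dis = numeric(0))
  if (nrow(ci) == 0L)
    return(new("CornerMatching", pairs = emptyPairs, totalDis = 0,
               nLeft = as.integer(nLeft), nRight = as.integer(nRight)))

  v1 <- sort(unique(ci$left))
  v2 <- sort(unique(ci$right))
  n <- max(length(v1), length(v2))
  big <- 1 + sum(ci$dis)
  cost <- matrix(big, n, n)
  li <- match(ci$left, v1)
  ri <- match(ci$right, v2)
  cost[cbind(li, ri)] <- ci$dis
  # infinitesimal lexicographic perturbation: prefer lower-index pairings
  # among equal-cost optima (never large enough to change the optimum set
  # for distances that differ by more than ~1e-6)
  pert <- 1e-9 * outer(seq_len(n), seq_len(n) / (n + 1), "+")
  assign <- cpp_solve_assignment(cost + pert)

  real <- which(seq_len(n) <= length(v1) & assign <= length(v2))
  real <- real[cost[cbind(real, assign[real])] < big]
  pairs <- data.frame(left = v1[real], right = v2[assign[real]],
                      dis = cost[cbind(real, assign[real])])
  pairs <- pairs[order(pairs$left, pairs$right), , drop = FALSE]
  rownames(pairs) <- NULL
  new("CornerMatching", pairs = pairs, totalDis = sum(pairs$dis),
      nLeft = as.integer(nLeft), nRight = as.integer(nRight))
}

#' Match two corner sets end to end
#'
#' Convenience wrapper: [initialMatches()] followed by [finalMatches()],
#' carrying the full corner counts through for the similarity weight.
#'
#' @param left,right [CornerSet-class] objects
#' @return a [CornerMatching-class]
#' @export
matchCorners <- function(left, right) {
  finalMatches(initialMatches(left, right),
               nLeft = nCorners(left), nRight = nCorners(right))
}
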