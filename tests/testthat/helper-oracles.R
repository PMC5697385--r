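# Independent oracles and generators used across the suite.

# a corner set with unique random positions and layer importances
randomCornerSet <- function(n, dims = c(30L, 30L), maxLayer = 3L,
                            id = "rnd") {
  if (n == 0L) {
    return(CornerDx:::newCornerSet(matrix(integer(0), ncol = 2),
                                   importance = numeric(0),
                                   response = numeric(0), theta = NA_real_,
                                   dim = dims, id = id))
  }
  pos <- sample.int(dims[1] * dims[2], n)
  m <- ((pos - 1L) %% dims[1]) + 1L
  n2 <- ((pos - 1L) %/% dims[1]) + 1L
  CornerDx:::newCornerSet(cbind(m, n2),
                          importance = 1 / sample.int(maxLayer, n, TRUE),
                          response = rep(NA_real_, n), theta = NA_real_,
                          dim = dims, id = id)
}

# Definition-level candidate filter: the O(|C||C'|) double loop
bruteForceInitial <- function(left, right) {
  out <- data.frame(left = integer(0), right = integer(0),
                    dis = numeric(0))
  cl <- cornerCoords(left); cr <- cornerCoords(right)
  ml <- mobility(left); mr <- mobility(right)
  for (i in seq_len(nCorners(left))) {
    for (j in seq_len(nCorners(right))) {
      d <- sqrt(sum((cl[i, ] - cr[j, ])^2))
      if (d <= ml[i] + mr[j])
        out <- rbind(out, data.frame(left = i, right = j, dis = d))
    }
  }
  rownames(out) <- NULL
  out
}

# Exhaustive enumeration over all matchings of the candidate edge list:
# maximum cardinality, then minimum total distance.
enumerateBestMatching <- function(ci) {
  n <- nrow(ci)
  best <- list(card = 0L, total = 0)
  rec <- function(k, usedL, usedR, card, total) {
    if (card > best$card ||
        (card == best$card && total < best$total - 1e-12)) {
      best <<- list(card = card, total = total)
    }
    if (k > n) return()
    if (card + (n - k + 1L) < best$card) return()  # cannot catch up
    e <- ci[k, ]
    if (!(e$left %in% usedL) && !(e$right %in% usedR))
      rec(k + 1L, c(usedL, e$left), c(usedR, e$right), card + 1L,
          total + e$dis)
    rec(k + 1L, usedL, usedR, card, total)
  }
  rec(1L, integer(0), integer(0), 0L, 0)
  best
}

# small toy image with texture at several gradient scales
randomToyImage <- function(rows = 48L, cols = 48L) {
  base <- matrix(stats::runif(rows * cols), rows, cols)
  sm <- CornerDx:::smooth2d(base, 2)
  x <- 0.5 * (sm - min(sm)) / (max(sm) - min(sm))
  # add a few sharp blobs so the magnitude histogram spans several bins
  for (i in 1:3) {
    r <- sample(5:(rows - 5), 1); cc <- sample(5:(cols - 5), 1)
    x[(r - 2):(r + 2), (cc - 2):(cc + 2)] <-
      x[(r - 2):(r + 2), (cc - 2):(cc + 2)] + 0.4
  }
  pmin(x, 1)
}

randomMTI <- function(rows = 48L, cols = 48L) {
  buildMTI(randomToyImage(rows, cols))
}
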