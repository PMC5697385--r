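test_that("mobility is the reciprocal importance, undefined at zero", {
  expect_identical(mobility(1), 1)
  expect_identical(mobility(1 / 3), 3)
  expect_error(mobility(0), "importance")
  expect_error(mobility(c(1, -0.5)), "importance")
})

test_that("the pair criterion compares distance with summed mobilities", {
  expect_true(isMatch(0, 0, 1, 0, 1, 1))        # dis 1 <= 2
  expect_false(isMatch(0, 0, 1, 5, 0, 1 / 2))   # dis 5 >  3
  expect_true(isMatch(3, 7, 1 / 3, 3, 7, 1))    # dis 0
})

test_that("initial matching equals the definition-level filter", {
  le <- randomCornerSet(0)
  ri <- randomCornerSet(5)
  expect_identical(nrow(initialMatches(le, ri)), 0L)
  expect_identical(nrow(initialMatches(ri, le)), 0L)

  set.seed(71)
  for (rep in 1:20) {
    a <- randomCornerSet(sample(3:10, 1))
    b <- randomCornerSet(sample(3:10, 1))
    got <- initialMatches(a, b)
    want <- bruteForceInitial(a, b)
    expect_equal(got, want)
  }
})

test_that("final matching is optimal against exhaustive enumeration", {
  empty <- data.frame(left = integer(0), right = integer(0),
                      dis = numeric(0))
  cm0 <- finalMatches(empty, nLeft = 0L, nRight = 0L)
  expect_identical(nrow(matchedPairs(cm0)), 0L)
  expect_identical(totalDistance(cm0), 0)

  set.seed(72)
  for (rep in 1:50) {
    a <- randomCornerSet(sample(2:8, 1), dims = c(18L, 18L), maxLayer = 2L)
    b <- randomCornerSet(sample(2:8, 1), dims = c(18L, 18L), maxLayer = 2L)
    ci <- initialMatches(a, b)
    if (nrow(ci) > 16) next
    cm <- finalMatches(ci, nCorners(a), nCorners(b))
    best <- enumerateBestMatching(ci)
    expect_identical(nrow(matchedPairs(cm)), best$card)
    expect_equal(totalDistance(cm), best$total, tolerance = 1e-6)
    # one-to-one
    expect_false(any(duplicated(matchedPairs(cm)$left)))
    expect_false(any(duplicated(matchedPairs(cm)$right)))
  }
})

test_that("matching is symmetric in cardinality and total distance", {
  set.seed(73)
  for (rep in 1:10) {
    a <- randomCornerSet(sample(4:12, 1))
    b <- randomCornerSet(sample(4:12, 1))
    ab <- matchCorners(a, b)
    ba <- matchCorners(b, a)
    expect_identical(nrow(matchedPairs(ab)), nrow(matchedPairs(ba)))
    expect_equal(totalDistance(ab), totalDistance(ba), tolerance = 1e-9)
  }
})

test_that("a well-separated set matches itself perfectly", {
  coords <- as.matrix(expand.grid(m = seq(2, 26, by = 8),
                                  n = seq(2, 26, by = 8)))
  cs <- CornerDx:::newCornerSet(coords,
                                importance = rep(1, nrow(coords)),
                                response = rep(NA_real_, nrow(coords)),
                                theta = NA_real_, dim = c(30L, 30L),
                                id = "grid")
  cm <- matchCorners(cs, cs)
  expect_identical(nrow(matchedPairs(cm)), nCorners(cs))
  expect_identical(totalDistance(cm), 0)
  expect_identical(matchedPairs(cm)$left, matchedPairs(cm)$right)
})
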