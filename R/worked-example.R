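#' Worked corner-matching example fixture
#'
#' A 12-versus-9 corner configuration reproducing the structure of the
#' reference worked matching example: the mobility-based candidate filter
#' yields exactly twelve initial pairs — including the four one-to-many
#' conflicts \[c1,c1'\]/\[c2,c1'\], \[c6,c5'\]/\[c7,c5'\],
#' \[c9,c7'\]/\[c10,c7'\] and \[c10,c8'\]/\[c11,c8'\] — with c5 and c4'
#' matching nothing, and the minimum-cost maximum-cardinality resolution
#' is exactly the eight pairs \[c1,c1'\], \[c3,c2'\], \[c4,c3'\],
#' \[c6,c5'\], \[c8,c6'\], \[c9,c7'\], \[c11,c8'\], \[c12,c9'\].
#'
#' The figure in the source is schematic (no printed coordinates), so the
#' coordinates and importance values here were synthesized once to
#' realize that printed adjacency and optimum; tests verify both against
#' the candidate-filter definition and an exhaustive-enumeration matching
#' oracle.
#'
#' @return list with `left` and `right` ([CornerSet-class], |C| = 12 and
#'   |C'| = 9), `ci` (expected initial pairs: data.frame left, right) and
#'   `cm` (expected final pairs: data.frame left, right)
#' @export
matchingExampleFixture <- function() {
  # importance 1 -> mobility 1; importance 1/2 -> mobility 2
  leftTab <- data.frame(
    m   = c(5, 5, 5, 5, 20, 20, 20, 20, 35, 35, 35, 35),
    n   = c(3, 8, 20, 35, 5, 18, 23, 35, 3, 9, 15, 35),
    imp = c(1, 1/2, 1/2, 1/2, 1, 1/2, 1/2, 1/2, 1/2, 1/2, 1/2, 1/2))
  rightTab <- data.frame(
    m   = c(5, 5, 7, 13, 20, 22, 35, 35, 37),
    n   = c(5, 22, 35, 10, 20, 35, 5, 13, 35),
    imp = c(1/2, 1/2, 1/2, 1, 1/2, 1/2, 1/2, 1/2, 1/2))

  mkSet <- function(tab, id) {
    cs <- newCornerSet(cbind(tab$m, tab$n), importance = tab$imp,
                       response = rep(NA_real_, nrow(tab)),
                       theta = NA_real_, dim = c(41L, 41L), id = id)
    # row-major storage order coincides with the c1..c12 numbering here
    stopifnot(all(cs@coords[, 1] == tab$m), all(cs@coords[, 2] == tab$n))
    cs
  }

  list(
    left = mkSet(leftTab, "example_C"),
    right = mkSet(rightTab, "example_Cprime"),
    ci = data.frame(
      left  = c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L, 10L, 10L, 11L, 12L),
      right = c(1L, 1L, 2L, 3L, 5L, 5L, 6L, 7L, 7L, 8L, 8L, 9L)),
    cm = data.frame(
      left  = c(1L, 3L, 4L, 6L, 8L, 9L, 11L, 12L),
      right = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L)))
}
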