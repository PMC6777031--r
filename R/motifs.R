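#' @include divergence.R
NULL

# Motif library for insertion-order permutations. A motif is a vector of
# integer multipliers of the system divergence fraction; a window of the
# local divergence-fraction sequence matches when every element equals the
# corresponding multiple of d* modulo 1, within tol.
#
# A single swap of adjacent nodes i, i+1 turns the constant gap sequence
# [..., d, d, d, ...] into [..., 2d, -d, 2d, ...] (mod 1). Two swaps of
# adjacent disjoint pairs (i, i+1) and (i+2, i+3) produce the five-gap
# signature [2d, -d, 3d, -d, 2d]; the four-gap form [2d, -d, -3d, 2d] is
# the conventional shorthand for the same event and both are recognized as
# DOUBLE_TWO_PERM.
.motifLibrary <- function() {
  list(
    list(kind = "DOUBLE_TWO_PERM", multiples = c(2, -1, 3, -1, 2)),
    list(kind = "DOUBLE_TWO_PERM", multiples = c(2, -1, -3, 2)),
    list(kind = "TWO_PERM", multiples = c(2, -1, 2))
  )
}

# circular distance on the unit circle of fractions
.circDist <- function(x, y) abs(((x - y + 0.5) %% 1) - 0.5)

#' Detect insertion-order permutation motifs
#'
#' Scans a sequence of successive divergence fractions for the signatures
#' left by permutations of the order in which primordia were inserted. With
#' system divergence fraction d*, a swap of two adjacent nodes (a
#' 2-permutation) leaves the gap motif [2d*, -d*, 2d*]; two adjacent
#' 2-permutations leave a double motif (see \code{kind}
#' \code{"DOUBLE_TWO_PERM"}). Every element is compared modulo 1 within
#' \code{tol}; longer motifs are matched preferentially, and windows
#' overlapping an already-matched longer motif are suppressed.
#'
#' @param fractions numeric vector of successive divergence fractions in
#'   [0, 1), e.g. from \code{\link{divergenceFractionSequence}}.
#' @param dStar the system divergence fraction.
#' @param tol matching tolerance, as a fraction of a full turn; must be
#'   positive and should stay below d*/2 to avoid aliasing.
#' @return data.frame with columns \code{start} (0-based index of the first
#'   gap of the match), \code{kind}, \code{length}, and \code{multiples}
#'   (comma-separated matched multiplier sequence); zero rows if nothing
#'   matches.
#' @examples
#' lat <- cylindricalLattice(143 * pi / 180, 1, 20)
#' detectPermutationMotifs(divergenceFractionSequence(lat), 143 / 360)
#' @export
detectPermutationMotifs <- function(fractions, dStar, tol = 0.02) {
  if (tol <= 0) stop("'tol' must be positive")
  L <- length(fractions)
  covered <- logical(L)
  out <- list()
  for (motif in .motifLibrary()) {
    ml <- length(motif$multiples)
    if (L < ml) next
    target <- (motif$multiples * dStar) %% 1
    for (s in seq_len(L - ml + 1L)) {
      idx <- s:(s + ml - 1L)
      if (any(covered[idx])) next
      if (all(.circDist(fractions[idx], target) <= tol)) {
        covered[idx] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          start = s - 1L, kind = motif$kind, length = ml,
          multiples = paste(motif$multiples, collapse = ","))
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), kind = character(),
                      length = integer(), multiples = character()))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
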