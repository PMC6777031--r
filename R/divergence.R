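#' @include lattice.R
NULL

# successive azimuth differences wrapped into [0, 2*pi) counter-clockwise
.gapsCCW <- function(theta) .wrap2pi(diff(theta))

#' Handedness of the genetic spiral
#'
#' The rotational direction, viewed from above (CCW = increasing theta), in
#' which the genetic spiral winds from the bottom of the specimen. Decided
#' from the mean counter-clockwise-wrapped successive azimuth difference:
#' below pi the spiral is counter-clockwise, above pi clockwise. A tie at
#' exactly pi resolves to CCW.
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 2 nodes.
#' @return "CCW" or "CW".
#' @export
handedness <- function(nodes) {
  if (nNodes(nodes) < 2L) stop("handedness needs at least 2 nodes")
  if (mean(.gapsCCW(nodeTheta(nodes))) <= pi) "CCW" else "CW"
}

#' Divergence angle statistics
#'
#' The divergence angle d is the mean angular step between successive
#' primordia (sorted by height), with every step wrapped into [0, 2*pi) in
#' the direction of the system's handedness so that d is comparable to the
#' golden angle regardless of chirality. The divergence fraction is
#' d* = d / 360.
#'
#' Two averaging rules are provided. \code{"as_printed"} (the default)
#' averages the q-2 steps between nodes 1..q-1, omitting the first gap;
#' \code{"all_gaps"} averages all q-1 successive steps. The standard error
#' uses the sample (n-1) standard deviation of the steps actually averaged.
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 3 nodes.
#' @param gapRule "as_printed" or "all_gaps"; see Details.
#' @return a list with elements \code{d} (degrees), \code{dStar},
#'   \code{se} (degrees), \code{localAngles} (all q-1 wrapped steps,
#'   degrees), \code{handedness}, \code{gapRule}.
#' @examples
#' lat <- cylindricalLattice(144 * pi / 180, rise = 1, q = 10)
#' divergenceStats(lat)$d  # 144, SE 0
#' @export
divergenceStats <- function(nodes, gapRule = c("as_printed", "all_gaps")) {
  gapRule <- match.arg(gapRule)
  q <- nNodes(nodes)
  if (q < 3L) stop("divergence statistics need at least 3 nodes")
  hand <- handedness(nodes)
  gaps <- .gapsCCW(nodeTheta(nodes))
  if (hand == "CW") gaps <- .wrap2pi(-gaps)
  used <- if (gapRule == "as_printed") gaps[-1L] else gaps
  dRad <- mean(used)
  se <- if (length(used) > 1L) stats::sd(used) / sqrt(length(used)) else 0
  list(d = dRad * 180 / pi,
       dStar = dRad / (2 * pi),
       se = se * 180 / pi,
       localAngles = gaps * 180 / pi,
       handedness = hand,
       gapRule = gapRule)
}

#' Rise (internode distance) statistics
#'
#' The rise between successive primordia is the axial internode distance
#' r_i = z_i - z_{i-1}. Returns all q-1 rises with their mean and standard
#' error (sample standard deviation over sqrt(q-1)).
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 2 nodes.
#' @return list with elements \code{rises} (cm), \code{mean}, \code{se}.
#' @export
riseStats <- function(nodes) {
  q <- nNodes(nodes)
  if (q < 2L) stop("rise statistics need at least 2 nodes")
  r <- diff(nodeZ(nodes))
  list(rises = r, mean = mean(r),
       se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0)
}

#' Successive divergence fractions
#'
#' The sequence of local divergence fractions: each successive azimuth step,
#' wrapped into [0, 1) of a turn in the handedness direction. This is the
#' sequence scanned for insertion-order permutation motifs.
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @return numeric vector of length q-1, values in [0, 1).
#' @seealso \code{\link{detectPermutationMotifs}}
#' @export
divergenceFractionSequence <- function(nodes) {
  gaps <- .gapsCCW(nodeTheta(nodes))
  if (handedness(nodes) == "CW") gaps <- .wrap2pi(-gaps)
  gaps / (2 * pi)
}

#' Swap the azimuths of two adjacent nodes
#'
#' Simulates a 2-permutation of the insertion order by exchanging the theta
#' values of nodes i and i+1 (0-based labels); z values, and hence labels,
#' are unchanged. Applying the same swap twice restores the original set.
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @param i 0-based label of the lower node of the pair; 0 <= i < q-1.
#' @return a new \code{NodeSet} with the pair of azimuths exchanged.
#' @export
swapAdjacentNodes <- function(nodes, i) {
  q <- nNodes(nodes)
  if (i < 0 || i >= q - 1) stop("'i' must satisfy 0 <= i < q-1")
  th <- nodeTheta(nodes)
  th[c(i + 1L, i + 2L)] <- th[c(i + 2L, i + 1L)]
  NodeSet(nodeZ(nodes), th, cylinderRadius(nodes))
}
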