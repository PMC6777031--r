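#' @include divergence.R
NULL

#' Parastichy family of a given order
#'
#' By the Bravais--Bravais theorem, adjacent primordia on an n-parastichy
#' have labels differing by n, so the n-parastichy family partitions the
#' labels 0..q-1 into the n residue classes mod n. The family direction is
#' taken from the sign of the mean wrapped azimuth step along the spirals
#' (positive = CCW).
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @param n family order, 1 <= n <= q.
#' @return list with elements \code{order}, \code{spirals} (list of n
#'   integer vectors of 0-based labels), \code{direction} ("CW"/"CCW").
#' @examples
#' lat <- cylindricalLattice(2.4, 1, 10)
#' parastichyFamily(lat, 2)$spirals  # {0,2,4,...}, {1,3,5,...}
#' @export
parastichyFamily <- function(nodes, n) {
  q <- nNodes(nodes)
  if (n < 1 || n > q) stop("'n' must satisfy 1 <= n <= q (empty spirals)")
  spirals <- lapply(seq_len(n) - 1L, function(j) seq(j, q - 1L, by = n))
  th <- nodeTheta(nodes)
  steps <- unlist(lapply(spirals, function(sp) {
    if (length(sp) < 2L) return(numeric())
    .wrapPi(diff(th[sp + 1L]))
  }))
  dir <- if (length(steps) && mean(steps) < 0) "CW" else "CCW"
  list(order = as.integer(n), spirals = spirals, direction = dir)
}

# local parastichy direction vectors of order k at each node, in the
# unrolled plane (x = radius * theta, z). Forward segment to label i+k when
# it exists, else backward from i-k; azimuth differences wrapped to
# (-pi, pi] so no segment spans more than half the circumference.
.familySegments <- function(nodes, k) {
  q <- nNodes(nodes)
  th <- nodeTheta(nodes); z <- nodeZ(nodes); R <- cylinderRadius(nodes)
  t(vapply(seq_len(q) - 1L, function(i) {
    if (i + k <= q - 1L) { a <- i; b <- i + k }
    else if (i - k >= 0L) { a <- i - k; b <- i }
    else return(c(NA_real_, NA_real_))
    c(R * .wrapPi(th[b + 1L] - th[a + 1L]), z[b + 1L] - z[a + 1L])
  }, numeric(2)))
}

#' Mean intersection angle between two parastichy families
#'
#' Unrolls the nodes to the plane (x = radius * theta, z) and, at every node
#' where both an m-family and an n-family segment are defined, measures the
#' angle between the two locally linearly-interpolated parastichy segments
#' via the law of cosines, folds it to the small angle min(a, 180 - a), and
#' returns the mean in degrees. On a perfectly regular lattice this equals
#' the closed-form angle between the lattice vectors
#' (see \code{\link{latticeVectorAngle}}).
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @param m,n distinct family orders; each family needs at least one defined
#'   segment (q > max(m, n)).
#' @return mean small intersection angle, degrees.
#' @export
familyIntersectionAngle <- function(nodes, m, n) {
  if (m == n) stop("'m' and 'n' must be distinct orders")
  q <- nNodes(nodes)
  if (q <= max(m, n))
    stop("family of order ", max(m, n), " is degenerate for q = ", q)
  u <- .familySegments(nodes, m)
  v <- .familySegments(nodes, n)
  ok <- stats::complete.cases(u) & stats::complete.cases(v)
  if (!any(ok)) stop("no node carries segments of both families")
  a2 <- rowSums(u[ok, , drop = FALSE]^2)
  b2 <- rowSums(v[ok, , drop = FALSE]^2)
  c2 <- rowSums((u[ok, , drop = FALSE] - v[ok, , drop = FALSE])^2)
  cosang <- pmin(1, pmax(-1, (a2 + b2 - c2) / (2 * sqrt(a2 * b2))))
  ang <- acos(cosang) * 180 / pi
  mean(pmin(ang, 180 - ang))
}

#' Closed-form lattice-vector intersection angle
#'
#' For a regular cylindrical lattice with divergence angle d (radians),
#' rise and radius, the order-k parastichy direction is the lattice vector
#' v_k = (radius * wrap(k d), k * rise) with wrap into (-pi, pi]. Returns
#' the small angle between v_m and v_n in degrees. Serves as the analytic
#' prediction of \code{\link{familyIntersectionAngle}} on noiseless
#' lattices.
#'
#' @param d divergence angle (radians).
#' @param rise internode distance (cm).
#' @param radius cylinder radius (cm).
#' @param m,n parastichy orders.
#' @return small intersection angle, degrees.
#' @export
latticeVectorAngle <- function(d, rise, radius, m, n) {
  vec <- function(k) c(radius * .wrapPi(k * d), k * rise)
  u <- vec(m); v <- vec(n)
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  min(ang, 180 - ang)
}

#' Conspicuous parastichy pair
#'
#' Among candidate visible-and-opposed pairs, the conspicuous pair is the
#' one whose families intersect at angles closest to 90 degrees. Ties break
#' toward the smaller pair (earlier candidate in the list, which for the
#' usual Fibonacci candidates means the smaller orders).
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @param candidates non-empty list of integer pairs, normally the output
#'   of \code{\link{visibleOpposedPairs}}.
#' @return list with \code{pair} (the winner), \code{angles} (named numeric
#'   of mean small angles per candidate, names "m,n").
#' @export
conspicuousPair <- function(nodes, candidates) {
  if (!length(candidates))
    stop("'candidates' is empty; compute visible and opposed pairs first")
  angles <- vapply(candidates, function(p)
    familyIntersectionAngle(nodes, p[1], p[2]), numeric(1))
  names(angles) <- vapply(candidates, paste, "", collapse = ",")
  best <- which.min(abs(angles - 90))  # first index wins ties
  list(pair = as.integer(candidates[[best]]), angles = angles)
}
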