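#' @include AllClasses.R AllGenerics.R
NULL

# wrap an angle (radians) into [0, 2*pi)
.wrap2pi <- function(x) {
  y <- x %% (2 * pi)
  # guard against 2*pi itself from floating point
  y[y >= 2 * pi] <- 0
  y
}

# wrap an angle (radians) into (-pi, pi]
.wrapPi <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

#' The golden angle
#'
#' 360 * (1 - 1/phi) degrees, where phi is the golden ratio; approximately
#' 137.5 degrees, the divergence angle of ideal Fibonacci phyllotaxy.
#'
#' @param degrees return degrees (default) or radians.
#' @return the golden angle.
#' @examples
#' round(goldenAngle(), 1)  # 137.5
#' @export
goldenAngle <- function(degrees = TRUE) {
  phi <- (1 + sqrt(5)) / 2
  g <- 360 * (1 - 1 / phi)
  if (degrees) g else g * pi / 180
}

#' Construct a NodeSet
#'
#' Builds the labeled-primordium container from raw cylinder coordinates.
#' Nodes are sorted by axial position; the label of a node is its 0-based
#' rank in that order. Azimuths are wrapped into [0, 2*pi).
#'
#' @param z axial positions (cm).
#' @param theta azimuths (radians); any real values, wrapped.
#' @param radius cylinder radius (cm).
#' @return a \code{\linkS4class{NodeSet}}.
#' @export
NodeSet <- function(z, theta, radius) {
  stopifnot(length(z) == length(theta))
  o <- order(z)
  new("NodeSet", z = as.numeric(z[o]), theta = .wrap2pi(as.numeric(theta[o])),
      radius = as.numeric(radius))
}

#' Centric (planar) phyllotactic spiral
#'
#' Generates idealized spiral nodes in the plane: node n (n = 0, ..., q-1)
#' sits at radius n and polar angle n*d, i.e. at
#' \code{(x_n, y_n) = (n cos(n d), n sin(n d))}. This is the sunflower-head
#' view of a spiral pattern; its cylindrical counterpart is
#' \code{\link{cylindricalLattice}}.
#'
#' @param d divergence angle in radians.
#' @param q number of nodes, at least 1.
#' @return a data.frame with columns n, x, y.
#' @examples
#' centricSpiral(goldenAngle(degrees = FALSE), 40)
#' @export
centricSpiral <- function(d, q) {
  if (!is.numeric(q) || length(q) != 1L || q < 1)
    stop("'q' must be a count >= 1")
  n <- seq_len(q) - 1
  data.frame(n = n, x = n * cos(n * d), y = n * sin(n * d))
}

#' Cylindrical Bravais lattice of primordia
#'
#' Generates the regular cylindrical lattice: node n at height n * rise and
#' azimuth (n * d) mod 2*pi. Unrolling the cylinder turns the helical
#' parastichies of this lattice into straight lines in the plane (the
#' Bravais lattice picture).
#'
#' @param d divergence angle in radians.
#' @param rise internode (axial) distance, in cm; must be positive.
#' @param q number of nodes.
#' @param radius cylinder radius (cm); defaults to 1.
#' @return a \code{\linkS4class{NodeSet}} with q nodes.
#' @examples
#' cylindricalLattice(goldenAngle(degrees = FALSE), rise = 1, q = 40)
#' @export
cylindricalLattice <- function(d, rise, q, radius = 1) {
  if (!is.numeric(q) || length(q) != 1L || q < 1)
    stop("'q' must be a count >= 1")
  if (!is.numeric(rise) || length(rise) != 1L || rise <= 0)
    stop("'rise' must be positive")
  n <- seq_len(q) - 1
  NodeSet(z = n * rise, theta = .wrap2pi(n * d), radius = radius)
}
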