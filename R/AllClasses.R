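#' @import methods
NULL

#' Tomographic trunk volume
#'
#' An ordered stack of 2D grayscale slices with voxel geometry. Slice 1 of the
#' array is the bottom of the specimen; intensities are normalized to [0, 1]
#' over the whole volume so that thresholds are comparable across slices.
#' Pixel coordinates in the public interface are 0-based \code{(x, y)} where x
#' indexes columns and y indexes rows.
#'
#' @slot data numeric 3D array \code{[row, col, slice]} with values in [0, 1].
#' @slot sliceThickness physical thickness of one slice (cm).
#' @slot pixelPitch side length of one (square) pixel (cm).
#'
#' @export
setClass("TrunkVolume",
  representation(data = "array", sliceThickness = "numeric",
                 pixelPitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "'data' must be a 3D array [row, col, slice]")
    rng <- suppressWarnings(range(object@data, finite = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      msg <- c(msg, "intensities must lie in [0, 1]")
    if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
      msg <- c(msg, "'sliceThickness' must be a positive scalar (cm)")
    if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
      msg <- c(msg, "'pixelPitch' must be a positive scalar (cm)")
    if (length(msg)) msg else TRUE
  })

#' Labeled primordia on the trunk cylinder
#'
#' Positions of primordia (epicormic traces) on the surface of an idealized
#' cylinder: axial position \code{z} in cm and azimuth \code{theta} in radians,
#' wrapped to [0, 2*pi). Nodes are stored sorted by z; the label of node i is
#' its 0-based rank in that order, matching the convention that node 0 is at
#' the bottom of the trunk.
#'
#' @slot z numeric, axial positions (cm), non-decreasing.
#' @slot theta numeric, azimuths (radians) in [0, 2*pi).
#' @slot radius cylinder radius (cm); the circumference is 2*pi*radius.
#'
#' @export
setClass("NodeSet",
  representation(z = "numeric", theta = "numeric", radius = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) != length(object@theta))
      msg <- c(msg, "'z' and 'theta' must have the same length")
    if (is.unsorted(object@z))
      msg <- c(msg, "'z' must be non-decreasing (nodes sorted by height)")
    if (length(object@theta) && (min(object@theta) < 0 ||
        max(object@theta) >= 2 * pi))
      msg <- c(msg, "'theta' must lie in [0, 2*pi)")
    if (length(object@radius) != 1L || object@radius <= 0)
      msg <- c(msg, "'radius' must be a positive scalar (cm)")
    if (length(msg)) msg else TRUE
  })

#' Cylinder-surface boundary image
#'
#' The per-slice radial summary B(i, theta): rows are slices (bottom first),
#' columns are angular bins of width \code{alpha} starting at theta = 0.
#' Columns wrap: bin 1 is adjacent to the last bin, so the image is the
#' unrolled surface of a cylinder and trace footprints appear as blobs.
#'
#' @slot data numeric matrix, rows = slices, cols = round(2*pi/alpha) bins,
#'   values in [0, 1].
#' @slot alpha angular bin width (radians).
#'
#' @export
setClass("BoundaryImage",
  representation(data = "matrix", alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || object@alpha <= 0)
      msg <- c(msg, "'alpha' must be a positive scalar (radians)")
    else if (ncol(object@data) != round(2 * pi / object@alpha))
      msg <- c(msg, "column count must equal round(2*pi/alpha)")
    rng <- suppressWarnings(range(object@data, finite = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      msg <- c(msg, "values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Segmented trace blobs
#'
#' Connected components of the thresholded boundary image. Centroid columns
#' are circular means so blobs straddling the theta = 0 seam are handled
#' correctly. Row/column coordinates are 0-based to match the boundary-image
#' indexing (row r is slice r, column c is angular bin c).
#'
#' @slot blobs data.frame with columns id, row, col, area, rescued.
#' @slot pixels list of 2-column integer matrices (0-based row, col), one per
#'   blob, mutually disjoint.
#' @slot dim integer dimensions (rows, cols) of the source image.
#'
#' @export
setClass("BlobSet",
  representation(blobs = "data.frame", pixels = "list", dim = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "row", "col", "area", "rescued")
    if (!all(need %in% names(object@blobs)))
      msg <- c(msg, paste("'blobs' must have columns",
                          paste(need, collapse = ", ")))
    if (length(object@pixels) != nrow(object@blobs))
      msg <- c(msg, "'pixels' must have one entry per blob")
    if (length(object@pixels) > 1L) {
      keys <- unlist(lapply(object@pixels,
                            function(p) p[, 1] * object@dim[2] + p[, 2]))
      if (anyDuplicated(keys))
        msg <- c(msg, "blob pixel sets must be disjoint")
    }
    if (length(msg)) msg else TRUE
  })

#' Phyllotaxy parameter record
#'
#' The summary record of a cylindrical phyllotactic system: divergence angle
#' and fraction, rise, handedness, visible-and-opposed parastichy pairs, the
#' conspicuous pair (family intersection angle closest to 90 degrees), the
#' conspicuous phyllotactic fraction A/B and the implied orthostichy count B.
#'
#' @slot q number of primordia.
#' @slot handedness "CW" or "CCW", direction of the genetic spiral from the
#'   bottom of the specimen.
#' @slot divergence list with elements d (degrees), dStar, se (degrees),
#'   localAngles (degrees).
#' @slot rise list with elements rises (cm), mean (cm), se (cm).
#' @slot visibleOpposed list of integer pairs (m, n).
#' @slot parastichyNumbers sorted integer vector of parastichy orders.
#' @slot conspicuousPair integer pair (m, n).
#' @slot conspicuousFraction integer pair (A, B).
#' @slot orthostichies integer, equals B.
#' @slot familyAngles named numeric, mean small intersection angle (degrees)
#'   per candidate pair, names "m,n".
#'
#' @export
setClass("PhyllotaxySummary",
  representation(q = "integer", handedness = "character",
                 divergence = "list", rise = "list",
                 visibleOpposed = "list", parastichyNumbers = "integer",
                 conspicuousPair = "integer", conspicuousFraction = "integer",
                 orthostichies = "integer", familyAngles = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@handedness %in% c("CW", "CCW"))
      msg <- c(msg, "'handedness' must be \"CW\" or \"CCW\"")
    if (length(object@conspicuousFraction) == 2L &&
        length(object@orthostichies) == 1L &&
        object@orthostichies != object@conspicuousFraction[2])
      msg <- c(msg, "'orthostichies' must equal the fraction denominator")
    if (length(msg)) msg else TRUE
  })
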