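#' @include AllClasses.R
NULL

#' @describeIn TrunkVolume number of slices in the stack.
#' @param object a \code{TrunkVolume}, \code{NodeSet}, \code{BoundaryImage}
#'   or \code{BlobSet}.
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @export
#' @describeIn TrunkVolume slice thickness (cm).
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))

#' @export
#' @describeIn TrunkVolume pixel pitch (cm).
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @export
#' @describeIn TrunkVolume extract slice \code{i} (1-based) as a matrix.
#' @param i slice index, 1-based from the bottom.
setGeneric("getSlice", function(object, i) standardGeneric("getSlice"))

#' @export
#' @describeIn NodeSet number of nodes q.
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @export
#' @describeIn NodeSet axial positions (cm), ascending.
setGeneric("nodeZ", function(object) standardGeneric("nodeZ"))

#' @export
#' @describeIn NodeSet azimuths (radians) in [0, 2*pi).
setGeneric("nodeTheta", function(object) standardGeneric("nodeTheta"))

#' @export
#' @describeIn NodeSet cylinder radius (cm).
setGeneric("cylinderRadius", function(object) standardGeneric("cylinderRadius"))

#' @export
#' @describeIn NodeSet cylinder circumference 2*pi*radius (cm).
setGeneric("circumference", function(object) standardGeneric("circumference"))

setMethod("nSlices", "TrunkVolume", function(object) dim(object@data)[3])
setMethod("sliceThickness", "TrunkVolume", function(object)
  object@sliceThickness)
setMethod("pixelPitch", "TrunkVolume", function(object) object@pixelPitch)
setMethod("getSlice", "TrunkVolume", function(object, i)
  object@data[, , i, drop = TRUE])

setMethod("nNodes", "NodeSet", function(object) length(object@z))
setMethod("nodeZ", "NodeSet", function(object) object@z)
setMethod("nodeTheta", "NodeSet", function(object) object@theta)
setMethod("cylinderRadius", "NodeSet", function(object) object@radius)
setMethod("circumference", "NodeSet", function(object) 2 * pi * object@radius)

#' @export
#' @describeIn NodeSet node table with columns label, z_cm, theta_rad.
#' @param x a \code{NodeSet}.
#' @param ... ignored.
setMethod("as.data.frame", "NodeSet", function(x, ...) {
  data.frame(label = seq_along(x@z) - 1L, z_cm = x@z, theta_rad = x@theta)
})

setMethod("show", "TrunkVolume", function(object) {
  d <- dim(object@data)
  cat("TrunkVolume:", d[3], "slices of", d[1], "x", d[2], "px\n")
  cat("  slice thickness:", object@sliceThickness, "cm;",
      "pixel pitch:", object@pixelPitch, "cm\n")
  cat("  intensity range: [", signif(min(object@data), 4), ", ",
      signif(max(object@data), 4), "]\n", sep = "")
})

setMethod("show", "NodeSet", function(object) {
  q <- length(object@z)
  cat("NodeSet:", q, "primordia on a cylinder of radius",
      signif(object@radius, 4), "cm\n")
  if (q) cat("  z: [", signif(min(object@z), 4), ", ",
             signif(max(object@z), 4), "] cm\n", sep = "")
})

setMethod("show", "BoundaryImage", function(object) {
  cat("BoundaryImage:", nrow(object@data), "slices x", ncol(object@data),
      "angular bins (alpha =", signif(object@alpha * 180 / pi, 4),
      "degrees)\n")
})

setMethod("show", "BlobSet", function(object) {
  cat("BlobSet:", nrow(object@blobs), "blobs (",
      sum(object@blobs$rescued), "rescued ) on a",
      object@dim[1], "x", object@dim[2], "boundary image\n")
})

setMethod("show", "PhyllotaxySummary", function(object) {
  fmt <- function(p) paste0("(", p[1], ",", p[2], ")")
  cat("Phyllotaxy summary\n")
  cat("  Number of primordia:      ", object@q, "\n")
  cat("  Handedness:               ",
      if (object@handedness == "CCW") "Counterclockwise" else "Clockwise",
      "\n")
  cat(sprintf("  Divergence angle (d):      %.3f deg +/- %.3f deg\n",
              object@divergence$d, object@divergence$se))
  cat(sprintf("  Divergence fraction (d*):  %.3f +/- %.3f\n",
              object@divergence$dStar, object@divergence$se / 360))
  cat(sprintf("  Average rise (r):          %.3f cm +/- %.3f cm\n",
              object@rise$mean, object@rise$se))
  cat("  Visible and opposed pairs: ",
      paste(vapply(object@visibleOpposed, fmt, ""), collapse = ", "), "\n")
  cat("  Parastichy numbers:       ",
      paste(object@parastichyNumbers, collapse = ", "), "\n")
  cat("  Conspicuous pair:         ", fmt(object@conspicuousPair), "\n")
  cat("  Conspicuous fraction:     ", paste(object@conspicuousFraction,
                                            collapse = "/"), "\n")
  cat("  Number of orthostichies:  ", object@orthostichies, "\n")
})
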