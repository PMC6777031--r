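#' @include AllClasses.R AllGenerics.R
NULL

# collapse an RGB(A) array to grayscale by channel mean
.toGray <- function(x) {
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3])),
                                         drop = FALSE], c(1, 2), mean)
  x
}

#' Min-max intensity normalization
#'
#' Rescales intensities linearly so the global minimum maps to 0 and the
#' global maximum to 1. A constant input is returned unchanged (clipped to
#' [0, 1]); the operation is idempotent on already-normalized data.
#'
#' @param x numeric array or matrix of intensities.
#' @return array of the same shape with values in [0, 1].
#' @export
normalizeIntensities <- function(x) {
  rng <- range(x, finite = TRUE)
  if (rng[2] > rng[1]) return((x - rng[1]) / (rng[2] - rng[1]))
  x[] <- pmin(1, pmax(0, x))   # keep dim attributes on the constant branch
  x
}

#' Read a tomographic slice stack
#'
#' Reads an ordered stack of 2D grayscale slices from a directory of
#' TIFF/PNG files or a single multi-page TIFF, and assembles a
#' \code{\linkS4class{TrunkVolume}}. Slices are ordered lexicographically
#' by filename (slice ordering metadata is format-dependent and not
#' available for TIFF/PNG, so \code{order = "by_metadata"} falls back to
#' filename order with a message). Raw intensities are min-max normalized
#' to [0, 1] over the whole volume, not per slice, so that intensity
#' thresholds are comparable across slices.
#'
#' @param path directory containing .tif/.tiff/.png slice files, or a
#'   single multi-page TIFF file.
#' @param sliceThickness physical slice thickness (cm); required.
#' @param pixelPitch pixel side length (cm); required.
#' @param order slice ordering rule; see Details.
#' @return a \code{\linkS4class{TrunkVolume}}; slice 1 is the bottom.
#' @export
readSliceStack <- function(path, sliceThickness, pixelPitch,
                           order = c("by_filename", "by_metadata")) {
  order <- match.arg(order)
  if (order == "by_metadata")
    message("no slice-location metadata in TIFF/PNG stacks; ",
            "ordering by filename")
  if (missing(sliceThickness) || missing(pixelPitch))
    stop("voxel geometry ('sliceThickness', 'pixelPitch') is required")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE))
        .toGray(png::readPNG(f))
      else .toGray(tiff::readTIFF(f))
    })
  } else if (file.exists(path)) {
    raw <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    slices <- lapply(raw, .toGray)
  } else stop("path does not exist: ", path)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed slice dimensions in stack: ",
         paste(unique(apply(dims, 2, paste, collapse = "x")),
               collapse = ", "))
  vol <- array(unlist(slices), dim = c(dims[1, 1], dims[2, 1],
                                       length(slices)))
  new("TrunkVolume", data = normalizeIntensities(vol),
      sliceThickness = sliceThickness, pixelPitch = pixelPitch)
}

#' Write a volume as a multi-page 16-bit TIFF
#'
#' @param volume a \code{\linkS4class{TrunkVolume}}.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeSliceStack <- function(volume, path) {
  slices <- lapply(seq_len(nSlices(volume)), function(i) getSlice(volume, i))
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a node table
#'
#' Reads a CSV with header \code{label,z_cm,theta_rad} into a
#' \code{\linkS4class{NodeSet}}. Azimuths equal to 2*pi (within 1e-12) are
#' wrapped to 0 with a warning; any other out-of-range or non-numeric row
#' is an error reporting the offending line numbers. An empty file yields
#' an empty NodeSet with a warning.
#'
#' @param path CSV path.
#' @param radius cylinder radius (cm) to attach; the CSV stores only node
#'   coordinates.
#' @return a \code{\linkS4class{NodeSet}}.
#' @export
readNodes <- function(path, radius = 1) {
  raw <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty node file: ", path)
    return(new("NodeSet", z = numeric(), theta = numeric(),
               radius = as.numeric(radius)))
  }
  need <- c("label", "z_cm", "theta_rad")
  if (!all(need %in% names(raw)))
    stop("node CSV must have header ", paste(need, collapse = ","))
  bad <- which(!is.finite(raw$z_cm) | !is.finite(raw$theta_rad))
  if (length(bad))
    stop("malformed node rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  th <- raw$theta_rad
  atTwoPi <- abs(th - 2 * pi) < 1e-12
  if (any(atTwoPi)) {
    warning("theta = 2*pi normalized to 0 at line(s) ",
            paste(which(atTwoPi) + 1L, collapse = ", "))
    th[atTwoPi] <- 0
  }
  out <- which(th < 0 | th >= 2 * pi)
  if (length(out))
    stop("theta outside [0, 2*pi) at line(s) ",
         paste(out + 1L, collapse = ", "), " of ", path)
  NodeSet(raw$z_cm, th, radius)
}

#' Write a node table
#'
#' Writes the \code{label,z_cm,theta_rad} CSV. The round trip through
#' \code{\link{readNodes}} is lossless to full double precision.
#'
#' @param nodes a \code{\linkS4class{NodeSet}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNodes <- function(nodes, path) {
  df <- as.data.frame(nodes)
  df$z_cm <- format(df$z_cm, digits = 17, trim = TRUE, scientific = FALSE)
  df$theta_rad <- format(df$theta_rad, digits = 17, trim = TRUE,
                         scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a boundary image
#'
#' Writes the boundary image as CSV (one row per slice, bottom first) and
#' optionally as a 16-bit grayscale TIFF raster.
#'
#' @param b a \code{\linkS4class{BoundaryImage}}.
#' @param csvPath CSV output path, or NULL to skip.
#' @param tiffPath 16-bit TIFF output path, or NULL to skip.
#' @return invisibly, a character vector of the paths written.
#' @export
writeBoundaryImage <- function(b, csvPath = NULL, tiffPath = NULL) {
  written <- character()
  if (!is.null(csvPath)) {
    utils::write.table(b@data, csvPath, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    written <- c(written, csvPath)
  }
  if (!is.null(tiffPath)) {
    tiff::writeTIFF(b@data, tiffPath, bits.per.sample = 16L)
    written <- c(written, tiffPath)
  }
  invisible(written)
}

#' Read a boundary image written by \code{\link{writeBoundaryImage}}
#'
#' @param csvPath CSV path.
#' @param alpha angular bin width (radians) of the stored image.
#' @return a \code{\linkS4class{BoundaryImage}}.
#' @export
readBoundaryImage <- function(csvPath, alpha) {
  m <- as.matrix(utils::read.table(csvPath, sep = ","))
  dimnames(m) <- NULL
  new("BoundaryImage", data = m, alpha = alpha)
}
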