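#' @include polar.R
NULL

#' Otsu threshold over a 256-bin histogram
#'
#' Computes the global Otsu threshold of an intensity image: intensities
#' are binned into \code{nbins} equal-width bins over [0, 1], and the bin
#' boundary maximizing the between-class variance
#' w0 * w1 * (mu0 - mu1)^2 is selected. Ties resolve to the lowest such
#' boundary. The mask convention is values >= threshold.
#'
#' @param x numeric matrix or vector with values in [0, 1]; must not be
#'   constant.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold, a bin boundary in (0, 1).
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  if (diff(range(v)) == 0)
    stop("image is constant; no Otsu threshold exists")
  counts <- tabulate(pmin(nbins, floor(v * nbins) + 1L), nbins)
  p <- counts / sum(counts)
  omega <- cumsum(p)                 # class-0 weight up to bin b
  mu <- cumsum(p * (seq_len(nbins) - 0.5) / nbins)
  muT <- mu[nbins]
  # between-class variance for cut after bin b = 1..nbins-1
  b <- seq_len(nbins - 1L)
  w0 <- omega[b]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma2 <- rep(-Inf, nbins - 1L)
  sigma2[valid] <- (muT * w0[valid] - mu[b][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(sigma2)
  best / nbins
}

#' Binarize a boundary image with Otsu's method
#'
#' @param b a \code{\linkS4class{BoundaryImage}} (or plain matrix) with
#'   non-constant values.
#' @param nbins histogram bins for the Otsu scan.
#' @return logical matrix: values >= the Otsu threshold.
#' @export
binarizeBoundary <- function(b, nbins = 256L) {
  m <- if (is(b, "BoundaryImage")) b@data else b
  m >= otsuThreshold(m, nbins)
}

# label connected components of a logical mask; columns wrap when wrapCols.
# Returns an integer matrix of labels (0 = background).
.labelComponents <- function(mask, connectivity = 8L, wrapCols = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- .neighborOffsets(connectivity)
  labels <- matrix(0L, nr, nc)
  queue <- integer(sum(mask))
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    head <- 1L; tail <- 1L
    queue[tail] <- start; tail <- tail + 1L
    labels[start] <- lab
    while (head < tail) {
      lin <- queue[head]; head <- head + 1L
      r <- ((lin - 1L) %% nr) + 1L
      c <- ((lin - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        if (wrapCols) cc <- ((cc - 1L) %% nc) + 1L
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- lab
          queue[tail] <- (cc - 1L) * nr + rr; tail <- tail + 1L
        }
      }
    }
  }
  labels
}

# circular mean of 0-based column indices on a ring of nc bins
.circMeanCol <- function(cols, nc) {
  ang <- cols * 2 * pi / nc
  m <- atan2(mean(sin(ang)), mean(cos(ang))) * nc / (2 * pi)
  m %% nc
}

#' Segment trace blobs in a binary boundary mask
#'
#' Extracts connected components (8-connectivity by default; traces are
#' compact) with the first and last columns treated as adjacent when
#' \code{wrap} is set, since the theta = 0 and theta = 2*pi rays of the
#' boundary image glue together. Components smaller than \code{minArea}
#' are dropped (their count is recorded in an attribute). Centroid columns
#' are circular means so seam-straddling blobs are placed correctly.
#'
#' @param mask logical matrix, e.g. from \code{\link{binarizeBoundary}}.
#' @param wrap treat columns as periodic (default TRUE).
#' @param minArea drop components with fewer pixels than this (default 4,
#'   suppressing speckle).
#' @param connectivity 8 (default) or 4.
#' @return a \code{\linkS4class{BlobSet}}; attribute \code{"dropped"}
#'   holds the number of under-sized components discarded.
#' @export
segmentBlobs <- function(mask, wrap = TRUE, minArea = 4L,
                         connectivity = 8L) {
  labels <- .labelComponents(mask, connectivity, wrap)
  nlab <- max(labels)
  pix <- vector("list", nlab)
  keep <- logical(nlab)
  rows <- cols <- areas <- numeric(nlab)
  for (l in seq_len(nlab)) {
    idx <- which(labels == l, arr.ind = TRUE)
    if (nrow(idx) < minArea) next
    keep[l] <- TRUE
    pix[[l]] <- cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
    rows[l] <- mean(idx[, 1] - 1L)
    cols[l] <- .circMeanCol(idx[, 2] - 1L, ncol(mask))
    areas[l] <- nrow(idx)
  }
  ord <- which(keep)
  bs <- new("BlobSet",
            blobs = data.frame(id = seq_along(ord) - 1L,
                               row = rows[ord], col = cols[ord],
                               area = as.integer(areas[ord]),
                               rescued = logical(length(ord))),
            pixels = pix[ord],
            dim = dim(mask))
  attr(bs, "dropped") <- sum(!keep & seq_len(nlab) > 0)
  bs
}

#' Rescue a faint blob with a local threshold
#'
#' A trace whose footprint is too faint for the global Otsu threshold can
#' be recovered by thresholding a small region of interest at a less
#' restrictive local percentile. The largest component of the thresholded
#' ROI is returned, flagged as rescued. ROIs are supplied manually (the
#' operator identifies the missed trace), mirroring a
#' human-in-the-loop correction; there is no automatic second pass.
#'
#' @param b a \code{\linkS4class{BoundaryImage}} or plain matrix.
#' @param roi 0-based inclusive window \code{c(row0, row1, col0, col1)}.
#' @param percentile local threshold percentile in (0, 100); the ROI is
#'   binarized at values >= this percentile of the ROI intensities.
#' @return list with \code{row}, \code{col} (0-based centroid in full-image
#'   coordinates), \code{area}, \code{pixels}, \code{rescued = TRUE}.
#' @export
rescueBlob <- function(b, roi, percentile = 80) {
  m <- if (is(b, "BoundaryImage")) b@data else b
  if (roi[1] < 0 || roi[3] < 0 || roi[2] >= nrow(m) || roi[4] >= ncol(m) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi window out of bounds")
  sub <- m[(roi[1]:roi[2]) + 1L, (roi[3]:roi[4]) + 1L, drop = FALSE]
  if (diff(range(sub)) == 0)
    stop("no signal in the ROI: no blob can be separated; ",
         "try a lower percentile or a different window")
  thr <- stats::quantile(sub, probs = percentile / 100, names = FALSE)
  mask <- sub >= thr
  labels <- .labelComponents(mask, 8L, wrapCols = FALSE)
  if (max(labels) == 0L)
    stop("no blob found in the ROI; try a lower percentile")
  sizes <- tabulate(labels[labels > 0L])
  idx <- which(labels == which.max(sizes), arr.ind = TRUE)
  pixels <- cbind(row = idx[, 1] - 1L + roi[1],
                  col = idx[, 2] - 1L + roi[3])
  list(row = mean(pixels[, "row"]),
       col = .circMeanCol(pixels[, "col"], ncol(m)),
       area = nrow(pixels), pixels = pixels, rescued = TRUE)
}

#' Append a rescued blob to a blob set
#'
#' @param blobSet a \code{\linkS4class{BlobSet}}.
#' @param blob a rescued blob from \code{\link{rescueBlob}}.
#' @return the extended \code{BlobSet}.
#' @export
addBlob <- function(blobSet, blob) {
  df <- blobSet@blobs
  df <- rbind(df, data.frame(id = nrow(df), row = blob$row, col = blob$col,
                             area = as.integer(blob$area), rescued = TRUE))
  new("BlobSet", blobs = df, pixels = c(blobSet@pixels, list(blob$pixels)),
      dim = blobSet@dim)
}

#' Convert blob centroids to cylinder nodes
#'
#' Inverts the boundary-image coordinates: a centroid at (row, col) becomes
#' a node at z = row * sliceThickness and theta = col * alpha wrapped to
#' [0, 2*pi). Nodes are sorted by z and labeled 0..q-1.
#'
#' @param blobs a \code{\linkS4class{BlobSet}}.
#' @param sliceThickness slice thickness (cm).
#' @param alpha angular bin width (radians).
#' @param radius cylinder radius (cm) to attach to the node set.
#' @param dupTol warn when two nodes coincide within this (z, theta)
#'   tolerance, as fractions of a slice and a bin respectively.
#' @return a \code{\linkS4class{NodeSet}}.
#' @export
blobsToNodes <- function(blobs, sliceThickness, alpha, radius,
                         dupTol = 0.5) {
  df <- blobs@blobs
  z <- df$row * sliceThickness
  th <- .wrap2pi(df$col * alpha)
  if (nrow(df) > 1L) {
    o <- order(z, th)
    dz <- diff(z[o]) / sliceThickness
    dt <- abs(.wrapPi(diff(th[o]))) / alpha
    if (any(dz < dupTol & dt < dupTol))
      warning("near-duplicate nodes detected within (",
              dupTol, " slice, ", dupTol, " bin)")
  }
  NodeSet(z, th, radius)
}
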