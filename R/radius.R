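#' @include pith.R
NULL

#' Sobel gradient magnitude
#'
#' Convolves the slice with the 3x3 horizontal and vertical Sobel kernels
#' and returns sqrt(gx^2 + gy^2). Image borders are handled by edge
#' replication so the frame of the image does not register as an edge.
#'
#' @param slice numeric matrix.
#' @return numeric matrix of the same dimensions.
#' @export
sobelMagnitude <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  # replicate-padded shifts
  up    <- slice[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- slice[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  shl <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]   # left nbr
  shr <- function(m) m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  # gx: column (x) derivative; gy: row (y) derivative
  gx <- (shr(up) + 2 * shr(slice) + shr(down)) -
        (shl(up) + 2 * shl(slice) + shl(down))
  gy <- (shl(down) + 2 * down + shr(down)) -
        (shl(up) + 2 * up + shr(up))
  sqrt(gx^2 + gy^2)
}

#' Estimate the trunk radius in one slice
#'
#' Applies Sobel edge detection, keeps only pixels whose gradient magnitude
#' reaches the given percentile of the whole slice's magnitude distribution
#' (computed over the full image, background included), and returns the
#' median Euclidean distance from the retained pixels to the pith center.
#' The bark/air boundary carries the strongest gradients, so at the default
#' 99th percentile the retained pixels concentrate on the rim and the
#' median distance estimates the trunk radius robustly even when interior
#' rings and traces also respond to the edge detector.
#'
#' @param slice numeric matrix.
#' @param center 0-based pith center \code{c(x, y)}.
#' @param percentile retention percentile in [0, 100); default 99.
#'   Percentile 0 keeps every pixel (degenerate: the median distance over
#'   the whole image).
#' @return estimated radius in pixels.
#' @export
estimateSliceRadius <- function(slice, center, percentile = 99) {
  if (percentile < 0 || percentile >= 100)
    stop("'percentile' must lie in [0, 100)")
  if (center[1] < 0 || center[1] > ncol(slice) - 1 ||
      center[2] < 0 || center[2] > nrow(slice) - 1)
    stop("pith center out of bounds")
  mag <- sobelMagnitude(slice)
  thr <- stats::quantile(mag, probs = percentile / 100, names = FALSE)
  keep <- which(mag >= thr, arr.ind = TRUE)
  if (!nrow(keep)) stop("no pixels retained at percentile ", percentile)
  dx <- (keep[, 2] - 1) - center[1]
  dy <- (keep[, 1] - 1) - center[2]
  stats::median(sqrt(dx^2 + dy^2))
}

#' Per-slice radius profile of the trunk
#'
#' Runs \code{\link{estimateSliceRadius}} on every slice against the
#' tracked pith centers.
#'
#' @param volume a \code{\linkS4class{TrunkVolume}}.
#' @param pith pith track data.frame from \code{\link{trackPith}}.
#' @param percentile Sobel retention percentile; see
#'   \code{\link{estimateSliceRadius}}.
#' @return data.frame with columns \code{slice} (0-based), \code{rho_px},
#'   \code{rho_cm}.
#' @export
radiusProfile <- function(volume, pith, percentile = 99) {
  n <- nSlices(volume)
  stopifnot(nrow(pith) == n)
  rho <- vapply(seq_len(n), function(i)
    estimateSliceRadius(getSlice(volume, i),
                        c(pith$x[i], pith$y[i]), percentile),
    numeric(1))
  data.frame(slice = seq_len(n) - 1L, rho_px = rho,
             rho_cm = rho * pixelPitch(volume))
}

#' Overall trunk radius with bootstrap standard error
#'
#' The overall radius is the median of the per-slice radii; its uncertainty
#' is the bootstrap standard error of the median (resampling slices with
#' replacement under a fixed seed).
#'
#' @param rho numeric vector of per-slice radii (any unit).
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{median} and \code{se}.
#' @export
overallRadius <- function(rho, nBoot = 1000L, seed = 0L) {
  if (!length(rho)) stop("need at least one slice radius")
  med <- stats::median(rho)
  se <- if (length(rho) > 1L) {
    boots <- withSeed(seed, {
      vapply(seq_len(nBoot), function(b)
        stats::median(sample(rho, replace = TRUE)), numeric(1))
    })
    stats::sd(boots)
  } else 0
  list(median = med, se = se)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' seeded internals (e.g. the radius bootstrap) do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
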