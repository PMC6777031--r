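#' @include blobs.R
NULL

#' Specification of a synthetic trunk phantom
#'
#' Describes a phantom tomographic volume with known phyllotactic ground
#' truth: a roughly circular trunk cross-section of wood-level intensity
#' with concentric ring texture, a dark pith near the center (optionally
#' drifting across slices), and thin high-intensity radial wedges (the
#' epicormic traces) at node positions laid out on a cylindrical lattice.
#' Additive Gaussian noise, clipped to [0, 1], controls difficulty.
#'
#' Defaults describe a desk-scale specimen geometrically similar to a
#' young cherry trunk: a 2.5 cm-radius trunk (50 px at 0.05 cm pitch)
#' bearing q = 20 nodes with divergence 143 degrees and rise 1.5 cm, ring
#' texture confined to the foreground intensity range, traces running from
#' the pith to the bark and spanning 3 slices in height, and noise sigma
#' 0.02.
#'
#' @param imageSize slice side length in pixels.
#' @param pixelPitch cm per pixel.
#' @param sliceThickness cm per slice.
#' @param trunkRadius trunk radius in pixels.
#' @param pithRadius pith radius in pixels.
#' @param pithStart 0-based (x, y) pith center in the bottom slice;
#'   defaults to the image center.
#' @param pithDrift per-slice (dx, dy) drift of the pith center in pixels.
#' @param nRings number of sinusoidal ring periods across the trunk radius.
#' @param d divergence angle in degrees.
#' @param rise internode distance in cm.
#' @param q number of nodes.
#' @param traceWidthDeg angular width of a trace wedge, degrees.
#' @param traceExtent radial extent of traces as a fraction of the trunk
#'   radius (1 = pith to bark).
#' @param traceHeightSlices trace height in slices.
#' @param backgroundLevel,pithLevel,woodLevel,ringAmp,traceLevel intensity
#'   levels; wood +/- ringAmp should stay inside the foreground range used
#'   downstream so rings are not mistaken for traces.
#' @param noiseSigma standard deviation of the additive Gaussian noise.
#' @param zMarginSlices slices of margin below the first and above the
#'   last trace.
#' @param seed RNG seed; the volume is a deterministic function of the
#'   spec including this seed.
#' @return a list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(imageSize = 128L, pixelPitch = 0.05,
                        sliceThickness = 0.25, trunkRadius = 50,
                        pithRadius = 4, pithStart = NULL,
                        pithDrift = c(0, 0), nRings = 8,
                        d = 143, rise = 1.5, q = 20L,
                        traceWidthDeg = 4, traceExtent = 1,
                        traceHeightSlices = 3L,
                        backgroundLevel = 0, pithLevel = 0.05,
                        woodLevel = 0.45, ringAmp = 0.12,
                        traceLevel = 0.9, noiseSigma = 0.02,
                        zMarginSlices = 3L, seed = 1L) {
  if (is.null(pithStart)) pithStart <- rep((imageSize - 1) / 2, 2)
  spec <- list(imageSize = as.integer(imageSize), pixelPitch = pixelPitch,
               sliceThickness = sliceThickness, trunkRadius = trunkRadius,
               pithRadius = pithRadius, pithStart = pithStart,
               pithDrift = pithDrift, nRings = nRings, d = d, rise = rise,
               q = as.integer(q), traceWidthDeg = traceWidthDeg,
               traceExtent = traceExtent,
               traceHeightSlices = as.integer(traceHeightSlices),
               backgroundLevel = backgroundLevel, pithLevel = pithLevel,
               woodLevel = woodLevel, ringAmp = ringAmp,
               traceLevel = traceLevel, noiseSigma = noiseSigma,
               zMarginSlices = as.integer(zMarginSlices),
               seed = as.integer(seed))
  if (spec$pithRadius >= spec$trunkRadius)
    stop("pith radius must be smaller than the trunk radius")
  if (spec$trunkRadius >= spec$imageSize / 2)
    stop("trunk radius must fit inside the image")
  class(spec) <- "PhantomSpec"
  spec
}

#' Generate a phantom trunk volume with ground truth
#'
#' Renders the volume described by a \code{\link{phantomSpec}} slice by
#' slice and returns it together with the exact node lattice, per-slice
#' pith centers and true radius, so every pipeline stage can be scored
#' against known truth. Identical spec (including seed) gives a
#' bit-identical volume.
#'
#' @param spec a \code{"PhantomSpec"}.
#' @return list with \code{volume} (a \code{\linkS4class{TrunkVolume}})
#'   and \code{truth}: \code{nodes} (a \code{\linkS4class{NodeSet}} on the
#'   cylinder of the true radius in cm), \code{pith} (data.frame slice, x,
#'   y), \code{radius_px}, \code{radius_cm}.
#' @export
generateTrunkVolume <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  th <- spec$sliceThickness
  n <- seq_len(spec$q) - 1
  z0 <- spec$zMarginSlices * th + spec$traceHeightSlices / 2 * th
  zNodes <- z0 + n * spec$rise
  thNodes <- .wrap2pi(n * spec$d * pi / 180)
  nSl <- if (spec$q == 0L) 2L * spec$zMarginSlices + 4L else
    ceiling(max(zNodes) / th + spec$traceHeightSlices / 2 +
              spec$zMarginSlices)

  size <- spec$imageSize
  xs <- matrix(rep(0:(size - 1), each = size), size)   # col index (x)
  ys <- matrix(rep(0:(size - 1), times = size), size)  # row index (y)
  h <- spec$traceHeightSlices
  centers <- cbind(x = spec$pithStart[1] + (seq_len(nSl) - 1) *
                     spec$pithDrift[1],
                   y = spec$pithStart[2] + (seq_len(nSl) - 1) *
                     spec$pithDrift[2])
  nodeSlice <- round(zNodes / th)   # central slice (0-based) of each trace

  vol <- withSeed(spec$seed, {
    arr <- array(spec$backgroundLevel, dim = c(size, size, nSl))
    for (i in seq_len(nSl)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      dx <- xs - cx; dy <- ys - cy
      dist <- sqrt(dx^2 + dy^2)
      img <- matrix(spec$backgroundLevel, size, size)
      inTrunk <- dist <= spec$trunkRadius
      img[inTrunk] <- spec$woodLevel + spec$ringAmp *
        sin(2 * pi * spec$nRings * dist[inTrunk] / spec$trunkRadius)
      img[dist <= spec$pithRadius] <- spec$pithLevel
      active <- which(abs((i - 1) - nodeSlice) <= (h - 1) / 2)
      if (length(active)) {
        ang <- atan2(dy, dx)
        for (k in active) {
          dAng <- abs(.wrapPi(ang - thNodes[k]))
          wedge <- dAng <= spec$traceWidthDeg / 2 * pi / 180 &
            dist >= spec$pithRadius &
            dist <= spec$traceExtent * spec$trunkRadius
          img[wedge] <- spec$traceLevel
        }
      }
      if (spec$noiseSigma > 0)
        img <- img + matrix(stats::rnorm(size * size, 0, spec$noiseSigma),
                            size, size)
      arr[, , i] <- pmin(1, pmax(0, img))
    }
    arr
  })

  truthNodes <- NodeSet(zNodes, thNodes,
                        radius = spec$trunkRadius * spec$pixelPitch)
  list(volume = new("TrunkVolume", data = vol, sliceThickness = th,
                    pixelPitch = spec$pixelPitch),
       truth = list(nodes = truthNodes,
                    pith = data.frame(slice = seq_len(nSl) - 1L,
                                      x = centers[, 1], y = centers[, 2]),
                    radius_px = spec$trunkRadius,
                    radius_cm = spec$trunkRadius * spec$pixelPitch))
}
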