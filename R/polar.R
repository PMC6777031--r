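#' @include radius.R
NULL

# nearest integer, rounding half away from zero (not banker's rounding)
.nint <- function(x) trunc(x + 0.5 * sign(x))

#' Resample a slice into polar coordinates about the pith
#'
#' Builds the polar slice P(r, theta) = Z(nint(x + r cos theta),
#' nint(y + r sin theta)) on the grid r in {0, s, 2s, ..., rho - s},
#' theta in {0, alpha, ..., 2*pi - alpha}, by nearest-integer sampling
#' (half away from zero). Radial wedge-shaped traces in the slice become
#' vertical high-intensity blocks in the polar slice. Samples falling
#' outside the image take the value 0 and are flagged background.
#'
#' @param slice numeric matrix.
#' @param center 0-based pith center \code{c(x, y)}.
#' @param rho slice radius in pixels; must exceed \code{s}.
#' @param alpha angular step (radians), positive; default 2*pi/720 (half a
#'   degree, sub-pixel arc at the rim for typical scan sizes).
#' @param s radial step (pixels), positive; default 0.5.
#' @return a list of class \code{"PolarSlice"} with elements \code{values}
#'   (matrix, rows = radii, cols = angular bins), \code{background}
#'   (logical matrix flagging out-of-bounds samples), \code{r},
#'   \code{theta}, \code{alpha}, \code{s}.
#' @export
polarSlice <- function(slice, center, rho, alpha = 2 * pi / 720, s = 0.5) {
  if (alpha <= 0 || s <= 0) stop("'alpha' and 's' must be positive")
  if (rho <= s) stop("'rho' must exceed the radial step 's'")
  r <- seq(0, rho - s, by = s)
  nTheta <- round(2 * pi / alpha)
  theta <- (seq_len(nTheta) - 1L) * alpha
  # sample grid: rows r, cols theta
  cx <- outer(r, cos(theta))            # r cos(theta)
  cy <- outer(r, sin(theta))
  px <- .nint(center[1] + cx)           # 0-based col
  py <- .nint(center[2] + cy)           # 0-based row
  outside <- px < 0 | px > ncol(slice) - 1 | py < 0 | py > nrow(slice) - 1
  lin <- ifelse(outside, 1L, py + 1L + px * nrow(slice))
  vals <- matrix(slice[lin], nrow = length(r))
  vals[outside] <- 0
  structure(list(values = vals, background = outside, r = r,
                 theta = theta, alpha = alpha, s = s),
            class = "PolarSlice")
}

# summarize one polar slice into a boundary-image row
.boundaryRow <- function(ps, Ti, stat, p) {
  v <- ps$values
  sel <- v >= Ti[1] & v <= Ti[2] & !ps$background
  vapply(seq_len(ncol(v)), function(j) {
    keep <- sel[, j]
    if (!any(keep)) return(0)
    x <- v[keep, j]
    switch(stat,
           mean = mean(x),
           median = stats::median(x),
           percentile = stats::quantile(x, probs = p / 100, names = FALSE),
           indicator = mean(keep))
  }, numeric(1))
}

#' Assemble a boundary image from polar slices
#'
#' The boundary image B(i, theta) summarizes each polar slice column
#' restricted to the foreground intensity range T (the part of the tree,
#' excluding background and pith): by default the mean of the qualifying
#' intensities; the median, a percentile, or the indicator mean (fraction
#' of qualifying samples) may be selected instead. Columns with no
#' qualifying sample are set to 0. Rows of the result are slices (bottom
#' first), columns are angular bins, and the two vertical edges of the
#' image glue together into a cylinder.
#'
#' @param polarSlices list of \code{"PolarSlice"} objects sharing alpha.
#' @param T foreground intensity range \code{c(lo, hi)}; may also be a
#'   2-column matrix with one row per slice for per-slice ranges.
#' @param stat summary statistic: "mean" (default), "median",
#'   "percentile", or "indicator".
#' @param p percentile (0-100) when \code{stat = "percentile"}.
#' @return a \code{\linkS4class{BoundaryImage}}.
#' @export
buildBoundaryImage <- function(polarSlices, T = c(0.2, 1),
                               stat = c("mean", "median", "percentile",
                                        "indicator"),
                               p = 75) {
  stat <- match.arg(stat)
  alphas <- vapply(polarSlices, `[[`, numeric(1), "alpha")
  if (any(abs(alphas - alphas[1]) > 1e-12))
    stop("polar slices disagree on the angular step alpha")
  Tm <- if (is.matrix(T)) T else
    matrix(T, nrow = length(polarSlices), ncol = 2, byrow = TRUE)
  if (any(Tm[, 1] > Tm[, 2]))
    warning("empty foreground range; affected rows are all zero")
  rows <- lapply(seq_along(polarSlices), function(i)
    .boundaryRow(polarSlices[[i]], Tm[i, ], stat, p))
  new("BoundaryImage", data = do.call(rbind, rows), alpha = alphas[1])
}

#' Boundary image straight from a volume
#'
#' Convenience wrapper running the polar transform slice by slice (without
#' keeping all polar slices in memory) and assembling the boundary image.
#'
#' @param volume a \code{\linkS4class{TrunkVolume}}.
#' @param pith pith track from \code{\link{trackPith}}.
#' @param rho per-slice radii in pixels (e.g. \code{rho_px} from
#'   \code{\link{radiusProfile}}), or a single number recycled.
#' @param T,stat,p see \code{\link{buildBoundaryImage}}.
#' @param alpha,s see \code{\link{polarSlice}}.
#' @return a \code{\linkS4class{BoundaryImage}}.
#' @export
boundaryImage <- function(volume, pith, rho, T = c(0.2, 1),
                          alpha = 2 * pi / 720, s = 0.5,
                          stat = "mean", p = 75) {
  n <- nSlices(volume)
  rho <- rep_len(rho, n)
  rows <- lapply(seq_len(n), function(i) {
    ps <- polarSlice(getSlice(volume, i), c(pith$x[i], pith$y[i]),
                     rho[i], alpha, s)
    .boundaryRow(ps, c(T[1], T[2]), stat, p)
  })
  new("BoundaryImage", data = do.call(rbind, rows), alpha = alpha)
}
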