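#' @include volume-io.R
NULL

# neighbor offsets as (drow, dcol); BFS visits in this fixed order so tie
# breaking is deterministic
.neighborOffsets <- function(connectivity) {
  four <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  if (connectivity == 4L) four
  else rbind(four, cbind(dr = c(-1L, -1L, 1L, 1L),
                         dc = c(-1L, 1L, -1L, 1L)))
}

# BFS flood over the full grid from 'start' (1-based c(row, col)) until a
# pixel satisfying 'hit' (logical matrix) is dequeued; returns its (row,col)
# or NULL. Ties at equal BFS depth resolve by enqueue order.
.bfsFirstHit <- function(hit, start, connectivity = 4L) {
  nr <- nrow(hit); nc <- ncol(hit)
  off <- .neighborOffsets(connectivity)
  visited <- matrix(FALSE, nr, nc)
  queue <- integer(nr * nc)
  head <- 1L; tail <- 1L
  queue[tail] <- (start[2] - 1L) * nr + start[1]; tail <- tail + 1L
  visited[start[1], start[2]] <- TRUE
  while (head < tail) {
    lin <- queue[head]; head <- head + 1L
    r <- ((lin - 1L) %% nr) + 1L
    c <- ((lin - 1L) %/% nr) + 1L
    if (hit[r, c]) return(c(r, c))
    for (k in seq_len(nrow(off))) {
      rr <- r + off[k, 1]; cc <- c + off[k, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
          !visited[rr, cc]) {
        visited[rr, cc] <- TRUE
        queue[tail] <- (cc - 1L) * nr + rr; tail <- tail + 1L
      }
    }
  }
  NULL
}

# connected component of TRUE pixels of 'mask' containing 'start'
# (1-based c(row, col)); returns a 2-column matrix of (row, col)
.componentAt <- function(mask, start, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- .neighborOffsets(connectivity)
  inComp <- matrix(FALSE, nr, nc)
  queue <- integer(sum(mask))
  head <- 1L; tail <- 1L
  queue[tail] <- (start[2] - 1L) * nr + start[1]; tail <- tail + 1L
  inComp[start[1], start[2]] <- TRUE
  while (head < tail) {
    lin <- queue[head]; head <- head + 1L
    r <- ((lin - 1L) %% nr) + 1L
    c <- ((lin - 1L) %/% nr) + 1L
    for (k in seq_len(nrow(off))) {
      rr <- r + off[k, 1]; cc <- c + off[k, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
          mask[rr, cc] && !inComp[rr, cc]) {
        inComp[rr, cc] <- TRUE
        queue[tail] <- (cc - 1L) * nr + rr; tail <- tail + 1L
      }
    }
  }
  which(inComp, arr.ind = TRUE)
}

#' Locate the pith in a single slice
#'
#' Runs a breadth-first flood fill from the seed pixel across the slice
#' until the nearest pixel whose intensity lies in the pith range \code{C}
#' is reached (ties resolved by BFS order), extracts the connected
#' component of in-range pixels containing that pixel, and returns the
#' component centroid. The pith is the dark hollow center of the trunk, so
#' \code{C} is a low-intensity range by default; being a range on
#' normalized intensities it is fully configuration-driven.
#'
#' @param slice numeric matrix (one slice), values in [0, 1].
#' @param seed 0-based pixel \code{c(x, y)} = (col, row) to seed the search.
#' @param C pith intensity range \code{c(lo, hi)}, a subset of [0, 1].
#' @param connectivity 4 (default) or 8, used for both the BFS and the
#'   component extraction.
#' @return centroid as \code{c(x, y)} in 0-based (possibly fractional)
#'   pixel coordinates.
#' @export
findPithInSlice <- function(slice, seed, C = c(0, 0.15),
                            connectivity = 4L) {
  stopifnot(length(C) == 2L, C[1] <= C[2])
  r0 <- as.integer(round(seed[2])) + 1L
  c0 <- as.integer(round(seed[1])) + 1L
  if (r0 < 1L || r0 > nrow(slice) || c0 < 1L || c0 > ncol(slice))
    stop("seed pixel out of bounds")
  inC <- slice >= C[1] & slice <= C[2]
  hit <- .bfsFirstHit(inC, c(r0, c0), connectivity)
  if (is.null(hit))
    stop("no pixel with intensity in [", C[1], ", ", C[2],
         "] reachable from the seed")
  comp <- .componentAt(inC, hit, connectivity)
  c(x = mean(comp[, 2]) - 1, y = mean(comp[, 1]) - 1)
}

#' Track the pith through the volume
#'
#' Finds the pith center slice by slice: the user marks the pith in the
#' bottom slice, and the centroid found in slice i seeds the flood-fill
#' search in slice i+1, exploiting the assumption that the pith does not
#' move significantly between slices.
#'
#' @param volume a \code{\linkS4class{TrunkVolume}}.
#' @param seed0 0-based \code{c(x, y)} pith seed for slice 1 (bottom).
#' @param C pith intensity range; see \code{\link{findPithInSlice}}.
#' @param connectivity 4 or 8.
#' @param onFail what to do when a slice has no reachable pith pixel:
#'   \code{"error"} (default) aborts naming the slice; \code{"reuse"}
#'   carries the previous center forward with a warning.
#' @return data.frame with columns \code{slice} (0-based), \code{x},
#'   \code{y} (0-based pixel centroids).
#' @export
trackPith <- function(volume, seed0, C = c(0, 0.15), connectivity = 4L,
                      onFail = c("error", "reuse")) {
  onFail <- match.arg(onFail)
  n <- nSlices(volume)
  xs <- numeric(n); ys <- numeric(n)
  seed <- seed0
  for (i in seq_len(n)) {
    ctr <- tryCatch(
      findPithInSlice(getSlice(volume, i), seed, C, connectivity),
      error = function(e) e)
    if (inherits(ctr, "error")) {
      if (onFail == "error" || i == 1L)
        stop("pith not found in slice ", i - 1L, ": ",
             conditionMessage(ctr))
      warning("pith not found in slice ", i - 1L,
              "; reusing previous center")
      ctr <- c(xs[i - 1L], ys[i - 1L])
    }
    xs[i] <- ctr[1]; ys[i] <- ctr[2]
    seed <- c(ctr[1], ctr[2])
  }
  data.frame(slice = seq_len(n) - 1L, x = xs, y = ys)
}
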