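#' @include rational.R
NULL

# Fibonacci sequence as used for parastichy pairs: F_1 = 1, F_2 = 2, 3, 5, ...
# (the classical sequence with the repeated leading 1 dropped); F_0 := 1.
.fib <- function(kMax) {
  f <- numeric(kMax + 2L)
  f[1] <- 1; f[2] <- 2
  if (kMax + 2L >= 3L)
    for (i in 3:(kMax + 2L)) f[i] <- f[i - 1] + f[i - 2]
  f   # f[k] = F_k
}

#' Adler visibility interval for a Fibonacci parastichy pair
#'
#' The parastichy pair (F_k, F_{k+1}) over the sequence (1, 2, 3, 5, 8, ...)
#' is visible and opposed exactly when the divergence fraction d* lies in
#' the interval I_k with endpoints F_{k-2}/F_k and F_{k-1}/F_{k+1} (in that
#' order for odd k, swapped for even k). Endpoints are computed and returned
#' in exact rational arithmetic. For k = 2 the leading endpoint uses
#' F_0 = 1; the pair (1, 2) at k = 1 is the classical special case with
#' interval [1/6, 1/2] (divergence angles between 60 and 180 degrees).
#'
#' @param k interval index, k >= 1.
#' @return list with elements \code{k}, \code{pair} (c(F_k, F_{k+1})),
#'   \code{lo}, \code{hi} (exact rationals, c(num, den)), and \code{range}
#'   (numeric endpoints).
#' @examples
#' adlerInterval(4)$range  # c(3/8, 2/5): the (5, 8) interval
#' @export
adlerInterval <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be an integer index >= 1")
  f <- .fib(max(k, 2L))
  F <- function(i) if (i == 0L) 1 else f[i]   # F_0 := 1
  pair <- c(F(k), F(k + 1L))
  if (k == 1L) {
    lo <- .rat(1, 6); hi <- .rat(1, 2)
  } else {
    a <- .rat(F(k - 2L), F(k))
    b <- .rat(F(k - 1L), F(k + 1L))
    if (k %% 2 == 1) { lo <- a; hi <- b } else { lo <- b; hi <- a }
  }
  list(k = k, pair = pair, lo = lo, hi = hi,
       range = c(.ratValue(lo), .ratValue(hi)))
}

#' Visible and opposed Fibonacci parastichy pairs
#'
#' All pairs (F_k, F_{k+1}) with 1 <= k <= kMax whose Adler interval
#' contains the divergence fraction d*. Membership is tested in exact
#' rational arithmetic against a rational approximation of d* at the stated
#' decimal precision; intervals are closed.
#'
#' @param dStar divergence fraction, 0 < dStar < 1.
#' @param kMax largest interval index considered.
#' @param digits decimal precision at which dStar is rationalized.
#' @return list of integer pairs c(m, n), in increasing k order.
#' @examples
#' visibleOpposedPairs(0.397, 4)  # (1,2), (2,3), (3,5), (5,8)
#' @export
visibleOpposedPairs <- function(dStar, kMax, digits = 9L) {
  if (dStar <= 0 || dStar >= 1) stop("'dStar' must lie in (0, 1)")
  if (kMax < 1) stop("'kMax' must be >= 1")
  d <- .ratFromDecimal(dStar, digits)
  out <- list()
  for (k in seq_len(kMax)) {
    iv <- adlerInterval(k)
    if (.ratLe(iv$lo, d) && .ratLe(d, iv$hi))
      out[[length(out) + 1L]] <- as.integer(iv$pair)
  }
  out
}

# candidate conspicuous fractions A/B = F_i / F_{i+2} over the classical
# sequence 1, 1, 2, 3, 5, 8, ...: 1/2, 1/3, 2/5, 3/8, 5/13, ...
.fractionCandidates <- function(maxIndex) {
  s <- numeric(maxIndex + 2L)
  s[1] <- 1; s[2] <- 1
  for (i in 3:(maxIndex + 2L)) s[i] <- s[i - 1] + s[i - 2]
  data.frame(i = seq_len(maxIndex), A = s[seq_len(maxIndex)],
             B = s[seq_len(maxIndex) + 2L])
}

#' Conspicuous phyllotactic fraction
#'
#' The Fibonacci fraction closest to the divergence fraction: among the
#' candidates F_i / F_{i+2} (1/2, 1/3, 2/5, 3/8, 5/13, ...), returns the
#' numerator/denominator pair minimizing |F_i/F_{i+2} - d*|. Ties break
#' toward the smaller index. The candidate scan stops at \code{maxIndex};
#' fractions with a denominator exceeding the number of observed nodes
#' cannot be resolved, so pass \code{maxIndex} accordingly when q is known.
#'
#' @param dStar divergence fraction in (0, 1).
#' @param maxIndex number of candidate fractions scanned (default 10, i.e.
#'   denominators up to 233).
#' @return integer pair c(A, B).
#' @examples
#' conspicuousFraction(0.397)  # c(2, 5)
#' @export
conspicuousFraction <- function(dStar, maxIndex = 10L) {
  if (dStar <= 0 || dStar >= 1) stop("'dStar' must lie in (0, 1)")
  cand <- .fractionCandidates(maxIndex)
  err <- abs(cand$A / cand$B - dStar)
  best <- which.min(err)   # which.min takes the first (smallest i) on ties
  as.integer(c(cand$A[best], cand$B[best]))
}

#' Orthostichy count of a phyllotactic fraction
#'
#' A phyllotactic fraction A/B means the genetic spiral makes A turns over
#' B successive nodes before a node recurs (approximately) on the same
#' vertical line; the stem therefore carries B vertical ranks of nodes
#' (orthostichies).
#'
#' @param fraction integer pair c(A, B).
#' @return B, the number of orthostichies.
#' @examples
#' orthostichyCount(c(2, 5))  # 5
#' @export
orthostichyCount <- function(fraction) {
  stopifnot(length(fraction) == 2L, fraction[2] > 0)
  as.integer(fraction[2])
}

#' Divergence angle implied by a phyllotactic fraction
#'
#' @param fraction integer pair c(A, B) with B > 0.
#' @return (A / B) * 360, in degrees.
#' @examples
#' fractionToAngle(c(2, 5))  # 144
#' @export
fractionToAngle <- function(fraction) {
  stopifnot(length(fraction) == 2L, fraction[2] > 0)
  fraction[1] / fraction[2] * 360
}
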