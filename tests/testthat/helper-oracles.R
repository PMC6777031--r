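# Independent oracles, deliberately written as plain brute-force loops so
# they share no code path with the implementation they check.

# Otsu by exhaustive scan: for every one of the 255 interior cut points of a
# 256-bin histogram on [0,1], compute the two class weights and the class
# means over the bin midpoints directly, and maximize w0*w1*(mu0-mu1)^2.
bruteForceOtsu <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  bin <- pmin(nbins, floor(v * nbins) + 1L)
  mids <- (bin - 0.5) / nbins
  best <- -Inf; bestCut <- NA_real_
  for (b in 1:(nbins - 1L)) {
    lo <- mids[bin <= b]; hi <- mids[bin > b]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s2 <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s2 > best + 1e-15) { best <- s2; bestCut <- b / nbins }
  }
  bestCut
}

# mean wrapped successive angle difference, enumerated by hand over the
# printed index range i = 1..q-2 (first gap skipped), CCW wrapping
bruteForceDivergenceCCW <- function(theta, skipFirst = TRUE) {
  q <- length(theta)
  gaps <- numeric(0)
  for (i in 1:(q - 1L)) {
    g <- (theta[i + 1L] - theta[i]) %% (2 * pi)
    gaps <- c(gaps, g)
  }
  if (skipFirst) gaps <- gaps[-1L]
  mean(gaps) * 180 / pi
}

# exact rational membership d* in [a1/a2, b1/b2] by cross multiplication,
# written against hand-derived Fibonacci interval endpoints
bruteForceAdlerMember <- function(num, den, k) {
  f <- c(1, 2, 3, 5, 8, 13, 21, 34, 55)   # F_1, F_2, ...
  F <- function(i) if (i == 0) 1 else f[i]
  if (k == 1) { e1 <- c(1, 6); e2 <- c(1, 2) }
  else {
    a <- c(F(k - 2), F(k)); b <- c(F(k - 1), F(k + 1))
    if (k %% 2 == 1) { e1 <- a; e2 <- b } else { e1 <- b; e2 <- a }
  }
  num * e1[2] >= e1[1] * den && num * e2[2] <= e2[1] * den
}

# Delaunay edges of a planar point set via scipy (qhull), as an independent
# triangulation engine; returns a character vector of "i-j" 1-based pairs
scipyDelaunayEdges <- function(x, y) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(data.frame(x = x, y = y), f, row.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys, numpy as np; from scipy.spatial import Delaunay; ",
    "p = np.loadtxt('", f, "', delimiter=',', skiprows=1); ",
    "t = Delaunay(p); e = set(); ",
    "[e.add((min(a,b)+1, max(a,b)+1)) for s in t.simplices ",
    "for a, b in ((s[0],s[1]), (s[1],s[2]), (s[0],s[2]))]; ",
    "print('\\n'.join(f'{a}-{b}' for a, b in sorted(e)))"))),
    stdout = TRUE)
  out
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- abs(((a - b + 180) %% 360) - 180)
  expect_lt(d, tol)
}
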