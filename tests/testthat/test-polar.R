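# slice with a bright wedge between two azimuths (degrees), pith to rim
wedgeSlice <- function(size = 100, center = c(50, 50), rim = 40,
                       from = 0, to = 30, hi = 1, bg = 0.4) {
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), times = size), size)
  dx <- xs - center[1]; dy <- ys - center[2]
  d <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  img <- matrix(0, size, size)
  img[d <= rim] <- bg
  img[d <= rim & ang >= from & ang <= to] <- hi
  img
}

test_that("polar resampling of constants and the r = 0 ray", {
  sl <- matrix(0.7, 50, 50)
  ps <- polarSlice(sl, c(25, 25), rho = 20)
  expect_true(all(ps$values == 0.7))
  sl[26, 26] <- 0.123   # pixel (x=25, y=25)
  ps2 <- polarSlice(sl, c(25, 25), rho = 20)
  expect_true(all(ps2$values[1, ] == 0.123))   # r = 0 row = center pixel
  expect_error(polarSlice(sl, c(25, 25), rho = 0.2), "rho")
  expect_error(polarSlice(sl, c(25, 25), rho = 20, alpha = -1), "alpha")
})

test_that("a radial wedge becomes a block of high-value columns", {
  sl <- wedgeSlice()
  ps <- polarSlice(sl, c(50, 50), rho = 40)
  colMean <- colMeans(ps$values)
  inWedge <- which(ps$theta >= 2 * pi / 180 & ps$theta <= 28 * pi / 180)
  outWedge <- which(ps$theta > 35 * pi / 180 & ps$theta < 2 * pi - 5 * pi / 180)
  expect_gt(min(colMean[inWedge]), 0.9)
  expect_lt(max(colMean[outWedge]), 0.5)
})

test_that("out-of-bounds samples are zero and flagged background", {
  sl <- matrix(0.5, 30, 30)
  ps <- polarSlice(sl, c(28, 15), rho = 25)
  expect_true(any(ps$background))
  expect_true(all(ps$values[ps$background] == 0))
})

test_that("boundary image summarizes foreground columns", {
  sl <- matrix(0.6, 40, 40)
  ps <- polarSlice(sl, c(20, 20), rho = 15)
  b <- buildBoundaryImage(list(ps, ps), T = c(0.2, 1))
  expect_true(all(abs(b@data - 0.6) < 1e-12))
  expect_equal(nrow(b@data), 2L)
  # empty foreground range -> all zero with warning
  expect_warning(b0 <- buildBoundaryImage(list(ps), T = c(0.9, 0.1)),
                 "empty")
  expect_true(all(b0@data == 0))
  # indicator summary gives the qualifying fraction
  bi <- buildBoundaryImage(list(ps), T = c(0.2, 1), stat = "indicator")
  expect_true(all(bi@data[1, ] > 0.9))
  psA <- polarSlice(sl, c(20, 20), rho = 15, alpha = 2 * pi / 360)
  expect_error(buildBoundaryImage(list(ps, psA)), "alpha")
})

test_that("rotating a slice circularly shifts its boundary row", {
  sl <- wedgeSlice(size = 101, center = c(50, 50), rim = 40)
  # rotate by +90 deg in pixel space: (x, y) -> (-y, x)
  rot <- t(sl)[, ncol(sl):1]
  alpha <- 2 * pi / 720
  row0 <- phyllotrunk:::.boundaryRow(
    polarSlice(sl, c(50, 50), 40, alpha), c(0.2, 1), "mean", 75)
  row90 <- phyllotrunk:::.boundaryRow(
    polarSlice(rot, c(50, 50), 40, alpha), c(0.2, 1), "mean", 75)
  shifts <- vapply(0:719, function(k) {
    shifted <- row0[((0:719 - k) %% 720) + 1]
    sum(abs(row90 - shifted))
  }, numeric(1))
  bestShift <- which.min(shifts) - 1L
  expect_lte(min(abs(c(bestShift - 180, bestShift - 180 + 720,
                       bestShift - 180 - 720))), 1)
})

test_that("traces are detectable against a trace-free phantom", {
  quiet <- generateTrunkVolume(smallPhantomSpec(q = 0L))
  traced <- generateTrunkVolume(smallPhantomSpec(q = 6L))
  rowSpread <- function(ph) {
    tr <- trackPith(ph$volume, c(47.5, 47.5))
    b <- boundaryImage(ph$volume, tr, ph$truth$radius_px)
    apply(b@data, 1, function(r) stats::sd(r) / mean(r))
  }
  cvQuiet <- rowSpread(quiet)
  cvTraced <- rowSpread(traced)
  expect_lt(max(cvQuiet), max(cvTraced))
})
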