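test_that("min-max normalization is linear, idempotent, and safe on constants", {
  x <- c(7, 57, 107)
  expect_equal(normalizeIntensities(x), c(0, 0.5, 1))
  expect_equal(normalizeIntensities(normalizeIntensities(x)),
               normalizeIntensities(x))
  expect_equal(normalizeIntensities(rep(0.5, 10)), rep(0.5, 10))
})

test_that("TIFF stack round-trips through write/read", {
  dirp <- withr::local_tempdir()
  vol <- new("TrunkVolume",
             data = array(runif(20 * 20 * 6), c(20, 20, 6)),
             sliceThickness = 0.1, pixelPitch = 0.05)
  vol@data[1, 1, 1] <- 0; vol@data[2, 2, 2] <- 1  # pin the range
  f <- file.path(dirp, "stack.tif")
  writeSliceStack(vol, f)
  back <- readSliceStack(f, sliceThickness = 0.1, pixelPitch = 0.05)
  expect_equal(nSlices(back), 6L)
  expect_lt(max(abs(back@data - vol@data)), 2 / 65535)
})

test_that("constant stacks are preserved, not stretched", {
  dirp <- withr::local_tempdir()
  vol <- new("TrunkVolume", data = array(0.5, c(8, 8, 3)),
             sliceThickness = 0.1, pixelPitch = 0.05)
  f <- file.path(dirp, "const.tif")
  writeSliceStack(vol, f)
  back <- readSliceStack(f, sliceThickness = 0.1, pixelPitch = 0.05)
  expect_equal(unique(as.vector(back@data)), 0.5, tolerance = 1e-4)
})

test_that("PNG directories read in filename order; mixed dims are an error", {
  dirp <- withr::local_tempdir()
  for (i in 1:4)
    png::writePNG(matrix(i / 10, 10, 10),
                  file.path(dirp, sprintf("s%02d.png", i)))
  vol <- readSliceStack(dirp, sliceThickness = 0.1, pixelPitch = 0.05)
  expect_equal(nSlices(vol), 4L)
  # after global min-max normalization slices span 0..1 in order
  expect_lt(max(abs(vol@data[1, 1, ] - c(0, 1, 2, 3) / 3)), 0.01)
  png::writePNG(matrix(0.5, 5, 5), file.path(dirp, "s99.png"))
  expect_error(readSliceStack(dirp, sliceThickness = 0.1,
                              pixelPitch = 0.05), "mixed")
  expect_error(readSliceStack(dirp), "geometry")
})

test_that("node CSV round-trip is lossless", {
  dirp <- withr::local_tempdir()
  set.seed(11)
  ns <- NodeSet(z = cumsum(runif(36, 0.5, 5)),
                theta = runif(36, 0, 2 * pi), radius = 4.72)
  f <- file.path(dirp, "nodes.csv")
  writeNodes(ns, f)
  back <- readNodes(f, radius = 4.72)
  expect_equal(nodeZ(back), nodeZ(ns), tolerance = 1e-9)
  expect_equal(nodeTheta(back), nodeTheta(ns), tolerance = 1e-9)
})

test_that("node CSV edge cases: empty file, theta wrap, malformed rows", {
  dirp <- withr::local_tempdir()
  empty <- file.path(dirp, "empty.csv")
  writeLines("label,z_cm,theta_rad", empty)
  expect_warning(ns <- readNodes(empty), "empty")
  expect_equal(nNodes(ns), 0L)
  wrapf <- file.path(dirp, "wrap.csv")
  writeLines(c("label,z_cm,theta_rad", "0,0,0",
               sprintf("1,1,%.17g", 2 * pi)), wrapf)
  expect_warning(ns2 <- readNodes(wrapf), "2\\*pi")
  expect_equal(nodeTheta(ns2), c(0, 0))
  badf <- file.path(dirp, "bad.csv")
  writeLines(c("label,z_cm,theta_rad", "0,0,0", "1,oops,1"), badf)
  expect_error(readNodes(badf), "line")
})

test_that("boundary image CSV export round-trips", {
  dirp <- withr::local_tempdir()
  b <- new("BoundaryImage", data = matrix(runif(5 * 720), 5), alpha = 2 * pi / 720)
  csv <- file.path(dirp, "b.csv"); tif <- file.path(dirp, "b.tif")
  writeBoundaryImage(b, csv, tif)
  back <- readBoundaryImage(csv, b@alpha)
  expect_equal(back@data, b@data, tolerance = 1e-12)
  expect_true(file.exists(tif))
})
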