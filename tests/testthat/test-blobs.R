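test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  two <- matrix(c(rep(0.2, 90), rep(0.8, 10)), 10)
  thr <- otsuThreshold(two)
  expect_true(thr > 0.2 && thr <= 0.8)
  expect_true(all((two >= thr) == (two == 0.8)))
  for (seed in 1:5) {
    set.seed(seed)
    img <- matrix(pmin(1, pmax(0, c(rnorm(300, 0.3, 0.08),
                                    rnorm(100, 0.75, 0.05)))), 20)
    expect_equal(otsuThreshold(img), bruteForceOtsu(img),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
  expect_error(otsuThreshold(matrix(0.4, 5, 5)), "constant")
})

test_that("Otsu agrees with the EBImage reference on random images", {
  set.seed(1)
  img <- matrix(runif(4096)^2, 64)
  ours <- otsuThreshold(img)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  expect_lt(abs(ours - ref), 1.5 / 256)
})

test_that("blob segmentation finds squares and seam-straddlers", {
  mask <- matrix(FALSE, 30, 720)
  mask[11:13, 21:23] <- TRUE   # 0-based rows 10-12, cols 20-22
  bs <- segmentBlobs(mask)
  expect_equal(nrow(bs@blobs), 1L)
  expect_equal(bs@blobs$row, 11)
  expect_equal(bs@blobs$col, 21)
  expect_equal(bs@blobs$area, 9L)
  # straddle the seam: cols 718, 719, 0, 1 (0-based)
  mask2 <- matrix(FALSE, 30, 720)
  mask2[5:7, c(719, 720, 1, 2)] <- TRUE
  wrapped <- segmentBlobs(mask2, wrap = TRUE)
  expect_equal(nrow(wrapped@blobs), 1L)
  expect_equal(wrapped@blobs$col %% 720, 719.5, tolerance = 1e-9)
  cut <- segmentBlobs(mask2, wrap = FALSE)
  expect_equal(nrow(cut@blobs), 2L)
})

test_that("small components are dropped by minArea", {
  mask <- matrix(FALSE, 20, 40)
  mask[2, 2] <- TRUE                    # speckle, area 1
  mask[10:12, 10:12] <- TRUE            # real blob
  bs <- segmentBlobs(mask, wrap = FALSE, minArea = 4)
  expect_equal(nrow(bs@blobs), 1L)
  expect_equal(attr(bs, "dropped"), 1)
})

test_that("segmentation commutes with circular column shifts", {
  set.seed(5)
  mask <- matrix(FALSE, 40, 360)
  for (k in 1:6) {
    r <- sample(3:36, 1); c <- sample(0:359, 1)
    rows <- r + (-1:1); cols <- ((c + (-2:2)) %% 360) + 1
    mask[rows, cols] <- TRUE
  }
  base <- segmentBlobs(mask)
  for (shift in c(37, 180, 359)) {
    shifted <- mask[, ((0:359 - shift) %% 360) + 1]
    bs <- segmentBlobs(shifted)
    expect_equal(nrow(bs@blobs), nrow(base@blobs))
    expect_equal(sort((base@blobs$col + shift) %% 360),
                 sort(bs@blobs$col %% 360), tolerance = 1e-9)
  }
})

test_that("faint blobs are rescued by a local threshold", {
  set.seed(21)
  img <- matrix(0.3 + rnorm(4000, 0, 0.015), 40, 100)
  img[10:13, 40:45] <- 0.9                    # strong blob
  img[30:32, 70:73] <- 0.45                   # faint blob, below Otsu
  thr <- otsuThreshold(img)
  expect_gt(thr, 0.45)                        # global threshold misses it
  bs <- segmentBlobs(img >= thr, wrap = FALSE)
  expect_equal(nrow(bs@blobs), 1L)
  res <- rescueBlob(img, roi = c(27, 35, 65, 80), percentile = 80)
  expect_true(res$rescued)
  expect_lt(abs(res$row - 31), 1.5)
  expect_lt(abs(res$col - 71.5), 1.5)
  # the rescued pixel set covers the true faint blob
  key <- paste(res$pixels[, "row"], res$pixels[, "col"])
  truth <- expand.grid(row = 29:31, col = 69:72)
  expect_true(all(paste(truth$row, truth$col) %in% key))
  full <- addBlob(bs, res)
  expect_equal(nrow(full@blobs), 2L)
  expect_equal(sum(full@blobs$rescued), 1L)
  expect_error(rescueBlob(matrix(0, 5, 5), c(0, 4, 0, 4)), "blob")
  expect_error(rescueBlob(img, c(0, 100, 0, 4)), "bounds")
})

test_that("blob centroids convert to cylinder nodes", {
  mkBlobs <- function(rows, cols) {
    new("BlobSet",
        blobs = data.frame(id = seq_along(rows) - 1L, row = rows,
                           col = cols, area = 9L,
                           rescued = logical(length(rows))),
        pixels = lapply(seq_along(rows), function(i)
          cbind(row = rows[i], col = cols[i])),
        dim = c(400L, 720L))
  }
  b <- mkBlobs(c(0, 160), c(0, 360))
  ns <- blobsToNodes(b, sliceThickness = 0.0625, alpha = pi / 360,
                     radius = 4.7)
  expect_equal(nodeZ(ns), c(0, 10))
  expect_equal(nodeTheta(ns), c(0, pi))
  dup <- mkBlobs(c(5, 5.2), c(10, 10.2))
  expect_warning(blobsToNodes(dup, 0.0625, pi / 360, 1), "duplicate")
})
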