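test_that("parastichy families are the residue classes of the labels", {
  lat <- cylindricalLattice(2.4, 1, 10)
  f2 <- parastichyFamily(lat, 2)
  expect_equal(f2$spirals, list(c(0L, 2L, 4L, 6L, 8L), c(1L, 3L, 5L, 7L, 9L)))
  f1 <- parastichyFamily(lat, 1)
  expect_equal(f1$spirals, list(0:9))   # the genetic spiral
  f3 <- parastichyFamily(lat, 3)
  expect_equal(lengths(f3$spirals), c(4L, 3L, 3L))
  expect_error(parastichyFamily(lat, 11), "empty")
})

test_that("families partition the labels for any order", {
  set.seed(3)
  for (rep in 1:8) {
    q <- sample(5:30, 1)
    n <- sample(1:q, 1)
    lat <- cylindricalLattice(runif(1, 0.1, 3), runif(1, 0.2, 2), q)
    fam <- parastichyFamily(lat, n)
    all_labels <- sort(unlist(fam$spirals))
    expect_equal(all_labels, 0:(q - 1))
    expect_equal(anyDuplicated(unlist(fam$spirals)), 0L)
  }
})

test_that("intersection angles on regular lattices match the closed form", {
  cases <- expand.grid(d = c(99.5, 137.5, 142.928, 151),
                       rise = c(0.6, 1.5, 2.896), radius = c(1, 4.72))
  for (i in seq_len(nrow(cases))) {
    d <- cases$d[i] * pi / 180
    lat <- cylindricalLattice(d, cases$rise[i], 25, cases$radius[i])
    for (pair in list(c(1, 2), c(2, 3), c(3, 5))) {
      expect_equal(familyIntersectionAngle(lat, pair[1], pair[2]),
                   latticeVectorAngle(d, cases$rise[i], cases$radius[i],
                                      pair[1], pair[2]),
                   tolerance = 1e-6)
    }
  }
})

test_that("a lattice built with perpendicular (1,2) vectors measures 90 deg", {
  # choose rise so v1 . v2 = 0: R^2 w(d) w(2d) + 2 rise^2 = 0
  dDeg <- 100; R <- 1
  d <- dDeg * pi / 180
  w <- function(a) ((a + pi) %% (2 * pi)) - pi
  rise <- sqrt(-R^2 * w(d) * w(2 * d) / 2)
  lat <- cylindricalLattice(d, rise, 20, R)
  expect_equal(familyIntersectionAngle(lat, 1, 2), 90, tolerance = 1e-6)
  cp <- conspicuousPair(lat, list(c(1, 2), c(2, 3)))
  expect_equal(cp$pair, c(1L, 2L))
})

test_that("conspicuous pair picks the family angle closest to 90 deg", {
  lat <- cylindricalLattice(143 * pi / 180, 1.5, 20, 2.5)
  cands <- list(c(1, 2), c(2, 3), c(3, 5), c(5, 8))
  cp <- conspicuousPair(lat, cands)
  # analytic winner from the closed-form lattice-vector angles
  ana <- vapply(cands, function(p)
    latticeVectorAngle(143 * pi / 180, 1.5, 2.5, p[1], p[2]), numeric(1))
  expect_equal(cp$pair, as.integer(cands[[which.min(abs(ana - 90))]]))
  expect_equal(cp$pair, c(2L, 3L))
  expect_error(conspicuousPair(lat, list()), "empty")
  expect_error(familyIntersectionAngle(lat, 3, 3), "distinct")
  expect_error(familyIntersectionAngle(cylindricalLattice(1, 1, 4), 2, 5),
               "degenerate")
})

test_that("cherry-parameter lattice has conspicuous pair (2,3)", {
  lat <- cherryLikeLattice()
  pairs <- visibleOpposedPairs(divergenceStats(lat)$dStar, 4)
  cp <- conspicuousPair(lat, pairs)
  expect_equal(cp$pair, c(2L, 3L))
  # angle ordering matches the reported measurements: (2,3) nearest 90,
  # then (3,5), then (5,8) progressively shallower
  a <- cp$angles
  expect_true(a[["2,3"]] > a[["3,5"]] && a[["3,5"]] > a[["5,8"]])
})
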