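test_that("periodic Delaunay edges carry Bravais label differences", {
  # near-square twisted lattice: neighbours one and two labels apart
  ts <- cylindricalLattice(170 * pi / 180, 1, 8, radius = 1)
  ed <- periodicDelaunay(ts)
  expect_true(all(c("label_a", "label_b", "order") %in% names(ed)))
  expect_true(all(ed$label_a < ed$label_b))
  expect_true(all(ed$order > 0))
  expect_equal(contactOrders(ed, 2), c(1L, 2L))
})

test_that("cherry-parameter lattice exhibits 1-, 2- and 3-contact parastichies", {
  lat <- cherryLikeLattice()
  ed <- periodicDelaunay(lat)
  expect_equal(sort(contactOrders(ed, 3)), c(1L, 2L, 3L))
})

test_that("a vertical stack has only 1-parastichy contacts", {
  st <- cylindricalLattice(0, 1, 8, radius = 1)
  expect_equal(contactOrders(periodicDelaunay(st)), 1L)
})

test_that("golden-angle lattice contacts are Fibonacci numbers", {
  lat <- cylindricalLattice(goldenAngle(FALSE), 1, 40,
                            radius = 40 / (2 * pi))
  orders <- contactOrders(periodicDelaunay(lat), 5)
  expect_true(all(orders %in% c(1L, 2L, 3L, 5L, 8L, 13L)))
})

test_that("the edge set is independent of the replica count", {
  lat <- cylindricalLattice(142.9 * pi / 180, 1.5, 24, radius = 2.5)
  e1 <- periodicDelaunay(lat, replicas = 1L, check = FALSE)
  e3 <- periodicDelaunay(lat, replicas = 3L, check = FALSE)
  expect_setequal(paste(e1$label_a, e1$label_b),
                  paste(e3$label_a, e3$label_b))
  # the built-in assertion passes silently
  expect_silent(periodicDelaunay(lat, check = TRUE))
})

test_that("the edge set is invariant to rotation and translation", {
  set.seed(8)
  lat <- cylindricalLattice(2.5, 1.1, 18, radius = 2)
  base <- periodicDelaunay(lat, check = FALSE)
  for (rot in c(0.7, 2.0, 4.4)) {
    moved <- NodeSet(nodeZ(lat) + 3.3, (nodeTheta(lat) + rot) %% (2 * pi),
                     cylinderRadius(lat))
    ed <- periodicDelaunay(moved, check = FALSE)
    expect_setequal(paste(base$label_a, base$label_b),
                    paste(ed$label_a, ed$label_b))
  }
})

test_that("our periodic edges match a scipy triangulation of the strip", {
  lat <- cylindricalLattice(143 * pi / 180, 1.5, 15, radius = 2.5)
  pts <- phyllotrunk:::.replicateStrip(lat, 1L)
  ref <- scipyDelaunayEdges(pts$x, pts$z)
  refIdx <- do.call(rbind, strsplit(ref, "-"))
  ia <- as.integer(refIdx[, 1]); ib <- as.integer(refIdx[, 2])
  central <- which(pts$rep == 0L)
  keep <- (ia %in% central | ib %in% central) &
    pts$label[ia] != pts$label[ib]
  refEdges <- unique(paste(pmin(pts$label[ia[keep]], pts$label[ib[keep]]),
                           pmax(pts$label[ia[keep]], pts$label[ib[keep]])))
  ours <- periodicDelaunay(lat)
  expect_setequal(paste(ours$label_a, ours$label_b), refEdges)
})

test_that("interior Voronoi cells of a regular lattice are congruent", {
  rise <- 1.5; R <- 2.5
  lat <- cylindricalLattice(143 * pi / 180, rise, 24, radius = R)
  cells <- voronoiCells(lat)
  expect_length(cells, 24L)
  # exclude cells near the open top/bottom ends of the strip
  interior <- Filter(function(cl) cl$bounded && cl$label >= 5 &&
                       cl$label <= 18, cells)
  areas <- vapply(interior, `[[`, numeric(1), "area")
  expect_gt(length(areas), 5)
  expect_lt(diff(range(areas)) / mean(areas), 1e-6)
  # lattice density: one node per rise of height over the circumference
  expect_equal(mean(areas), 2 * pi * R * rise, tolerance = 1e-6)
})

test_that("boundary cells are flagged unbounded and a degenerate set errors", {
  lat <- cylindricalLattice(143 * pi / 180, 1.5, 12, radius = 2.5)
  cells <- voronoiCells(lat)
  bounded <- vapply(cells, `[[`, logical(1), "bounded")
  expect_false(bounded[1])               # bottom node clipped by window
  expect_false(bounded[12])              # top node clipped by window
  expect_error(periodicDelaunay(cylindricalLattice(1, 1, 3)), "4 nodes")
})
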