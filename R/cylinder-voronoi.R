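#' @include parastichy.R
NULL

# unroll nodes to the plane and replicate left/right: returns data.frame
# x, z, label (0-based), rep (replica shift index)
.replicateStrip <- function(nodes, replicas) {
  th <- nodeTheta(nodes); z <- nodeZ(nodes)
  circ <- circumference(nodes)
  x0 <- cylinderRadius(nodes) * th
  shifts <- -replicas:replicas
  do.call(rbind, lapply(shifts, function(k)
    data.frame(x = x0 + k * circ, z = z,
               label = seq_along(z) - 1L, rep = k)))
}

.delaunayEdges <- function(pts) {
  dd <- tryCatch(deldir::deldir(pts$x, pts$z, suppressMsge = TRUE),
                 error = function(e)
                   stop("Delaunay triangulation failed (degenerate/",
                        "collinear input?): ", conditionMessage(e)))
  dd
}

#' Periodic Delaunay contact edges on the cylinder
#'
#' Unrolls the node set to the plane (x = radius * theta, z), replicates
#' every point one circumference to each side, triangulates the replicated
#' strip, and keeps the edges with at least one endpoint in the central
#' copy, deduplicated over periodic images and with self-edges (a node to
#' its own image) removed. Each edge joins two primordia that are Voronoi
#' neighbours on the cylinder surface, i.e. lie on a common contact
#' parastichy; by the Bravais--Bravais theorem its parastichy order is the
#' absolute label difference of its endpoints.
#'
#' One replica per side suffices when the strip is taller than it is wide;
#' by default the result is verified against a two-replica triangulation
#' and an error is raised if they disagree (short/wide strips).
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 4 nodes.
#' @param replicas periodic copies per side (default 1).
#' @param check verify replica-count independence against
#'   \code{replicas + 1} (default TRUE).
#' @return data.frame with columns \code{label_a}, \code{label_b}
#'   (0-based, a < b), \code{order} = |label_a - label_b|.
#' @export
periodicDelaunay <- function(nodes, replicas = 1L, check = TRUE) {
  if (nNodes(nodes) < 4L) stop("need at least 4 nodes")
  edgesFor <- function(reps) {
    pts <- .replicateStrip(nodes, reps)
    dd <- .delaunayEdges(pts)
    e <- dd$delsgs[, c("ind1", "ind2")]
    central <- which(pts$rep == 0L)
    keep <- e$ind1 %in% central | e$ind2 %in% central
    la <- pts$label[e$ind1[keep]]
    lb <- pts$label[e$ind2[keep]]
    sel <- la != lb
    a <- pmin(la[sel], lb[sel]); b <- pmax(la[sel], lb[sel])
    unique(data.frame(label_a = a, label_b = b))
  }
  ed <- edgesFor(replicas)
  if (check) {
    ed2 <- edgesFor(replicas + 1L)
    if (!setequal(paste(ed$label_a, ed$label_b),
                  paste(ed2$label_a, ed2$label_b)))
      stop("edge set changed with more periodic replicas; ",
           "increase 'replicas' for this short/wide strip")
  }
  ed <- ed[order(ed$label_a, ed$label_b), ]
  rownames(ed) <- NULL
  ed$order <- abs(ed$label_b - ed$label_a)
  ed
}

#' Dominant contact-parastichy orders
#'
#' Tallies the parastichy orders of the periodic Delaunay edges and
#' returns the \code{topK} most frequent, descending by multiplicity with
#' ties to the smaller order. These are the contact parastichies the
#' primordium packing exhibits.
#'
#' @param edges edge data.frame from \code{\link{periodicDelaunay}}.
#' @param topK how many orders to report (default 3).
#' @return integer vector of orders.
#' @export
contactOrders <- function(edges, topK = 3L) {
  if (!nrow(edges)) stop("empty edge set")
  tab <- table(edges$order)
  ord <- as.integer(names(tab))
  o <- order(-as.integer(tab), ord)
  utils::head(ord[o], topK)
}

# polygon area by the shoelace formula
.polyArea <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Periodic Voronoi cells on the cylinder strip
#'
#' Voronoi cells of the primordia computed on the unrolled periodic strip,
#' as a proxy for primordium "shape". The strip is periodic in theta only,
#' so cells at the top and bottom of the specimen are clipped by the
#' bounding window and marked unbounded; their areas are not meaningful
#' and are excluded from partition checks.
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 4 nodes.
#' @param replicas periodic copies per side (default 1).
#' @return list of cells, one per node in label order; each a list with
#'   \code{label}, \code{x}, \code{z} (polygon vertices), \code{area},
#'   \code{bounded}.
#' @export
voronoiCells <- function(nodes, replicas = 1L) {
  if (nNodes(nodes) < 4L) stop("need at least 4 nodes")
  pts <- .replicateStrip(nodes, replicas)
  zr <- range(pts$z); xr <- range(pts$x)
  mz <- max(diff(zr), 1) * 0.2; mx <- max(diff(xr), 1) * 0.2
  dd <- deldir::deldir(pts$x, pts$z, rw = c(xr[1] - mx, xr[2] + mx,
                                            zr[1] - mz, zr[2] + mz),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  central <- which(pts$rep == 0L)
  lapply(central, function(i) {
    tl <- tiles[[i]]
    onWindow <- any(tl$bp)
    list(label = pts$label[i], x = tl$x, z = tl$y,
         area = .polyArea(tl$x, tl$y), bounded = !onWindow)
  })
}

#' Export a contact edge list
#'
#' @param edges data.frame from \code{\link{periodicDelaunay}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEdges <- function(edges, path) {
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export Voronoi cells as polygon JSON
#'
#' Writes each cell as a loop of (x, z) vertices together with its label,
#' area and boundedness flag.
#'
#' @param cells list from \code{\link{voronoiCells}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCells <- function(cells, path) {
  jsonlite::write_json(cells, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
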