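# Shared fixtures, built in code at test time.

# lattice with the parameters measured on the cherry specimen
cherryLikeLattice <- function(q = 36) {
  cylindricalLattice(142.928 * pi / 180, rise = 2.896, q = q,
                     radius = 4.72)
}

# small, fast phantom for module-level pipeline tests
smallPhantomSpec <- function(...) {
  args <- list(imageSize = 96L, trunkRadius = 38, pithRadius = 3,
               q = 12L, rise = 1.2, sliceThickness = 0.25,
               pixelPitch = 0.05)
  do.call(phantomSpec, utils::modifyList(args, list(...)))
}

# run the imaging pipeline in memory on a generated phantom and return the
# recovered NodeSet together with the ground truth
recoverPhantom <- function(spec) {
  ph <- generateTrunkVolume(spec)
  vol <- ph$volume
  seed0 <- c(spec$pithStart[1], spec$pithStart[2])
  track <- trackPith(vol, seed0)
  prof <- radiusProfile(vol, track)
  ov <- overallRadius(prof$rho_cm)
  b <- boundaryImage(vol, track, prof$rho_px)
  blobs <- segmentBlobs(binarizeBoundary(b))
  nodes <- blobsToNodes(blobs, sliceThickness(vol), b@alpha, ov$median)
  list(nodes = nodes, truth = ph$truth, boundary = b, radius = ov,
       blobs = blobs, pith = track)
}
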