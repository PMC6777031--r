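#' @include summary.R phantom.R
NULL

#' Pipeline configuration
#'
#' Builds the configuration record driving \code{\link{runStage}}. Values
#' may come from a YAML or JSON file (\code{file}) and/or be overridden by
#' \code{...}; anything unspecified takes the documented default. All
#' intensity ranges refer to globally min-max normalized intensities.
#'
#' @param file optional YAML/JSON configuration file.
#' @param ... named overrides of individual fields.
#' @return list of class \code{"PipelineConfig"}. Fields: \code{input}
#'   (slice stack path), \code{sliceThickness}, \code{pixelPitch},
#'   \code{outDir}, \code{pithSeed} (0-based x, y), \code{C} (pith
#'   intensity range), \code{T} (foreground range), \code{alpha} (radians),
#'   \code{s} (pixels), \code{sobelPercentile}, \code{otsuBins},
#'   \code{minArea}, \code{wrap}, \code{rescue} (list of
#'   \code{list(roi, percentile)}), \code{gapRule}, \code{kMax},
#'   \code{motifTol}, \code{bootN}, \code{bootSeed}, \code{polarSlices}
#'   (0-based slice indices exported by the polar stage), \code{phantom}
#'   (arguments for \code{\link{phantomSpec}}, used by the simulate
#'   stage), \code{summaryStat}, \code{connectivity}.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- list(input = NULL, sliceThickness = NULL, pixelPitch = NULL,
              outDir = ".", pithSeed = NULL, C = c(0, 0.15),
              T = c(0.2, 1), alpha = 2 * pi / 720, s = 0.5,
              sobelPercentile = 99, otsuBins = 256L, minArea = 4L,
              wrap = TRUE, rescue = list(), gapRule = "as_printed",
              kMax = 6L, motifTol = 0.02, bootN = 1000L, bootSeed = 0L,
              polarSlices = integer(), phantom = list(),
              summaryStat = "mean", connectivity = 4L)
  if (!is.null(file)) {
    loaded <- if (grepl("\\.json$", file, ignore.case = TRUE))
      jsonlite::read_json(file, simplifyVector = TRUE)
    else yaml::read_yaml(file)
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$s > 0,
            all(cfg$C >= 0 & cfg$C <= 1), all(cfg$T >= 0 & cfg$T <= 1))
  class(cfg) <- "PipelineConfig"
  cfg
}

.artifact <- function(cfg, name) file.path(cfg$outDir, name)

.needArtifact <- function(cfg, name, producedBy) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run stage '", producedBy,
         "' first", call. = FALSE)
  p
}

.writeManifest <- function(cfg, stage, params, inputs = character()) {
  man <- list(stage = stage,
              package_version = as.character(
                utils::packageVersion("phyllotrunk")),
              parameters = params,
              input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(man, .artifact(cfg, paste0("manifest_", stage,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA)
}

.loadVolume <- function(cfg) {
  readSliceStack(cfg$input, sliceThickness = cfg$sliceThickness,
                 pixelPitch = cfg$pixelPitch)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Orchestrates the end-to-end analysis with per-stage artifacts on disk.
#' Each stage reads the artifacts of its upstream stages from
#' \code{outDir}, writes its own CSV/TIFF/JSON outputs there, and records
#' the parameters used in a stage manifest; re-running a stage with
#' unchanged inputs and configuration reproduces its artifacts
#' byte-for-byte.
#'
#' Stages: \code{simulate} (render the configured phantom and write it as
#' the input stack plus ground-truth tables), \code{pith} (track the pith;
#' writes pith.csv), \code{radius} (per-slice radii and overall median
#' with bootstrap SE; radius.csv, radius_overall.json), \code{polar}
#' (export polar transforms of the slices selected in
#' \code{polarSlices}), \code{boundary} (boundary.csv / boundary.tif),
#' \code{detect} (Otsu + blobs + rescues; blobs.csv, nodes.csv),
#' \code{phyllo} (summary.json, motifs.csv), \code{voronoi} (edges.csv,
#' cells.json), \code{all} (everything in order, without \code{polar}).
#'
#' @param stage stage name; see Details.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return invisibly, the primary object computed by the stage (e.g. the
#'   \code{\linkS4class{PhyllotaxySummary}} for \code{phyllo}/\code{all}).
#' @export
runStage <- function(stage = c("all", "simulate", "pith", "radius",
                               "polar", "boundary", "detect", "phyllo",
                               "voronoi"),
                     cfg, quiet = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", stage, "] ", ...)

  if (stage == "all") {
    runStage("pith", cfg, quiet)
    runStage("radius", cfg, quiet)
    runStage("boundary", cfg, quiet)
    runStage("detect", cfg, quiet)
    s <- runStage("phyllo", cfg, quiet)
    runStage("voronoi", cfg, quiet)
    return(invisible(s))
  }

  if (stage == "simulate") {
    spec <- do.call(phantomSpec, cfg$phantom)
    say("rendering phantom: ", spec$q, " nodes, d = ", spec$d, " deg")
    ph <- generateTrunkVolume(spec)
    writeSliceStack(ph$volume, .artifact(cfg, "phantom.tif"))
    writeNodes(ph$truth$nodes, .artifact(cfg, "truth_nodes.csv"))
    utils::write.csv(ph$truth$pith, .artifact(cfg, "truth_pith.csv"),
                     row.names = FALSE, quote = FALSE)
    .writeManifest(cfg, stage, spec[order(names(spec))])
    return(invisible(ph))
  }

  if (stage == "pith") {
    if (is.null(cfg$input)) stop("config field 'input' is required")
    vol <- .loadVolume(cfg)
    seed <- cfg$pithSeed
    if (is.null(seed)) stop("config field 'pithSeed' is required")
    say("tracking pith through ", nSlices(vol), " slices")
    track <- trackPith(vol, seed, cfg$C, cfg$connectivity)
    utils::write.csv(track, .artifact(cfg, "pith.csv"),
                     row.names = FALSE, quote = FALSE)
    .writeManifest(cfg, stage,
                   list(C = cfg$C, pithSeed = seed,
                        connectivity = cfg$connectivity), cfg$input)
    return(invisible(track))
  }

  if (stage == "radius") {
    pithPath <- .needArtifact(cfg, "pith.csv", "pith")
    pith <- utils::read.csv(pithPath)
    vol <- .loadVolume(cfg)
    say("estimating per-slice radii (Sobel p", cfg$sobelPercentile, ")")
    prof <- radiusProfile(vol, pith, cfg$sobelPercentile)
    utils::write.csv(prof, .artifact(cfg, "radius.csv"),
                     row.names = FALSE, quote = FALSE)
    ov <- overallRadius(prof$rho_cm, cfg$bootN, cfg$bootSeed)
    jsonlite::write_json(ov, .artifact(cfg, "radius_overall.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeManifest(cfg, stage,
                   list(sobelPercentile = cfg$sobelPercentile,
                        bootN = cfg$bootN, bootSeed = cfg$bootSeed),
                   .artifact(cfg, "pith.csv"))
    return(invisible(ov))
  }

  if (stage == "polar") {
    pithPath <- .needArtifact(cfg, "pith.csv", "pith")
    radPath <- .needArtifact(cfg, "radius.csv", "radius")
    pith <- utils::read.csv(pithPath)
    prof <- utils::read.csv(radPath)
    vol <- .loadVolume(cfg)
    idx <- if (length(cfg$polarSlices)) cfg$polarSlices
           else round(stats::quantile(0:(nSlices(vol) - 1L),
                                      c(0.25, 0.5, 0.75)))
    for (i in idx) {
      ps <- polarSlice(getSlice(vol, i + 1L),
                       c(pith$x[i + 1L], pith$y[i + 1L]),
                       prof$rho_px[i + 1L], cfg$alpha, cfg$s)
      utils::write.table(ps$values,
                         .artifact(cfg, sprintf("polar_%05d.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    .writeManifest(cfg, stage, list(alpha = cfg$alpha, s = cfg$s,
                                    slices = as.integer(idx)))
    return(invisible(idx))
  }

  if (stage == "boundary") {
    pithPath <- .needArtifact(cfg, "pith.csv", "pith")
    radPath <- .needArtifact(cfg, "radius.csv", "radius")
    pith <- utils::read.csv(pithPath)
    prof <- utils::read.csv(radPath)
    vol <- .loadVolume(cfg)
    say("building boundary image (", round(2 * pi / cfg$alpha),
        " angular bins)")
    b <- boundaryImage(vol, pith, prof$rho_px, cfg$T, cfg$alpha, cfg$s,
                       cfg$summaryStat)
    writeBoundaryImage(b, .artifact(cfg, "boundary.csv"),
                       .artifact(cfg, "boundary.tif"))
    .writeManifest(cfg, stage, list(T = cfg$T, alpha = cfg$alpha,
                                    s = cfg$s, stat = cfg$summaryStat),
                   c(.artifact(cfg, "pith.csv"),
                     .artifact(cfg, "radius.csv")))
    return(invisible(b))
  }

  if (stage == "detect") {
    bPath <- .needArtifact(cfg, "boundary.csv", "boundary")
    b <- readBoundaryImage(bPath, cfg$alpha)
    ovPath <- .needArtifact(cfg, "radius_overall.json", "radius")
    radCm <- jsonlite::read_json(ovPath)$median
    mask <- binarizeBoundary(b, cfg$otsuBins)
    blobs <- segmentBlobs(mask, cfg$wrap, cfg$minArea)
    for (r in cfg$rescue)
      blobs <- addBlob(blobs, rescueBlob(b, unlist(r$roi),
                                         r$percentile))
    say("detected ", nrow(blobs@blobs), " blobs (",
        sum(blobs@blobs$rescued), " rescued)")
    utils::write.csv(blobs@blobs, .artifact(cfg, "blobs.csv"),
                     row.names = FALSE, quote = FALSE)
    nodes <- blobsToNodes(blobs, cfg$sliceThickness, cfg$alpha, radCm)
    writeNodes(nodes, .artifact(cfg, "nodes.csv"))
    .writeManifest(cfg, stage,
                   list(otsuBins = cfg$otsuBins, minArea = cfg$minArea,
                        wrap = cfg$wrap, nRescue = length(cfg$rescue)),
                   c(.artifact(cfg, "boundary.csv"), ovPath))
    return(invisible(nodes))
  }

  if (stage == "phyllo") {
    ovPath <- file.path(cfg$outDir, "radius_overall.json")
    radCm <- if (file.exists(ovPath)) jsonlite::read_json(ovPath)$median
             else 1
    nodesPath <- .needArtifact(cfg, "nodes.csv", "detect")
    nodes <- readNodes(nodesPath, radCm)
    s <- summarizePhyllotaxy(nodes, cfg$gapRule, cfg$kMax)
    writeSummary(s, .artifact(cfg, "summary.json"))
    motifs <- detectPermutationMotifs(divergenceFractionSequence(nodes),
                                      s@divergence$dStar, cfg$motifTol)
    utils::write.csv(motifs, .artifact(cfg, "motifs.csv"),
                     row.names = FALSE, quote = FALSE)
    say("d = ", round(s@divergence$d, 3), " deg; conspicuous pair (",
        paste(s@conspicuousPair, collapse = ","), ")")
    .writeManifest(cfg, stage, list(gapRule = cfg$gapRule,
                                    kMax = cfg$kMax,
                                    motifTol = cfg$motifTol),
                   .artifact(cfg, "nodes.csv"))
    return(invisible(s))
  }

  if (stage == "voronoi") {
    ovPath <- file.path(cfg$outDir, "radius_overall.json")
    radCm <- if (file.exists(ovPath)) jsonlite::read_json(ovPath)$median
             else 1
    nodesPath <- .needArtifact(cfg, "nodes.csv", "detect")
    nodes <- readNodes(nodesPath, radCm)
    edges <- periodicDelaunay(nodes)
    writeEdges(edges, .artifact(cfg, "edges.csv"))
    writeCells(voronoiCells(nodes), .artifact(cfg, "cells.json"))
    say("contact orders: ",
        paste(contactOrders(edges), collapse = ", "))
    .writeManifest(cfg, stage, list(replicas = 1L),
                   .artifact(cfg, "nodes.csv"))
    return(invisible(edges))
  }
}

#' Run the full pipeline
#'
#' \code{runStage("all", cfg)}: pith, radius, boundary, detect, phyllo,
#' voronoi in order.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return the \code{\linkS4class{PhyllotaxySummary}}, invisibly.
#' @export
runPipeline <- function(cfg, quiet = FALSE) runStage("all", cfg, quiet)
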