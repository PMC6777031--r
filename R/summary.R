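#' @include cylinder-voronoi.R fibonacci.R motifs.R
NULL

#' Full phyllotaxy parameter summary of a node set
#'
#' Runs the whole lattice analysis on a set of primordium positions:
#' handedness, divergence angle/fraction and rise with standard errors,
#' visible-and-opposed Fibonacci parastichy pairs (Adler intervals),
#' per-pair mean family intersection angles, the conspicuous pair (angle
#' closest to 90 degrees), the conspicuous phyllotactic fraction (closest
#' Fibonacci fraction to d*) and the implied orthostichy count.
#'
#' Candidate pairs whose larger order is not smaller than q are dropped
#' before the angle comparison (their families are degenerate); candidate
#' conspicuous fractions are scanned only while their denominators do not
#' exceed q, since finer fractions are unresolvable from q nodes.
#'
#' @param nodes a \code{\linkS4class{NodeSet}} with at least 3 nodes.
#' @param gapRule divergence averaging rule; see
#'   \code{\link{divergenceStats}}.
#' @param kMax largest Adler interval index scanned.
#' @return a \code{\linkS4class{PhyllotaxySummary}}.
#' @export
summarizePhyllotaxy <- function(nodes, gapRule = "as_printed", kMax = 6L) {
  q <- nNodes(nodes)
  dstats <- divergenceStats(nodes, gapRule)
  rstats <- riseStats(nodes)
  pairs <- visibleOpposedPairs(dstats$dStar, kMax)
  usable <- Filter(function(p) max(p) < q, pairs)
  if (!length(usable))
    stop("no visible-and-opposed pair has non-degenerate families for q = ",
         q)
  cp <- conspicuousPair(nodes, usable)
  cand <- .fractionCandidates(15L)
  maxIdx <- max(1L, sum(cand$B <= q))
  frac <- conspicuousFraction(dstats$dStar, maxIdx)
  new("PhyllotaxySummary",
      q = as.integer(q),
      handedness = dstats$handedness,
      divergence = dstats[c("d", "dStar", "se", "localAngles")],
      rise = list(rises = rstats$rises, mean = rstats$mean, se = rstats$se),
      visibleOpposed = pairs,
      parastichyNumbers = sort(unique(unlist(pairs))),
      conspicuousPair = cp$pair,
      conspicuousFraction = frac,
      orthostichies = orthostichyCount(frac),
      familyAngles = cp$angles)
}

#' Serialize a phyllotaxy summary to JSON
#'
#' Writes the summary record (primordium count, handedness, divergence
#' angle/fraction with standard errors, rise, parastichy pairs and
#' numbers, conspicuous pair and fraction, orthostichies, per-pair
#' intersection angles) as a JSON object.
#'
#' @param summary a \code{\linkS4class{PhyllotaxySummary}}.
#' @param path output path, or NULL to return the list instead.
#' @return the list representation, invisibly when written.
#' @export
writeSummary <- function(summary, path = NULL) {
  rec <- list(
    number_of_primordia = summary@q,
    handedness = if (summary@handedness == "CCW") "Counterclockwise"
                 else "Clockwise",
    divergence_angle_deg = summary@divergence$d,
    divergence_angle_se_deg = summary@divergence$se,
    divergence_fraction = summary@divergence$dStar,
    divergence_fraction_se = summary@divergence$se / 360,
    average_rise_cm = summary@rise$mean,
    average_rise_se_cm = summary@rise$se,
    visible_opposed_pairs = summary@visibleOpposed,
    parastichy_numbers = summary@parastichyNumbers,
    conspicuous_parastichy_pair = summary@conspicuousPair,
    conspicuous_phyllotactic_fraction = paste(summary@conspicuousFraction,
                                              collapse = "/"),
    number_of_orthostichies = summary@orthostichies,
    family_intersection_angles_deg = as.list(summary@familyAngles))
  if (is.null(path)) return(rec)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
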