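# Invasion assay: nucleus detection across z-stacks and invasion-depth
# profiles.

#' Detect nuclei in stained z-stacks
#'
#' Finds connected above-threshold 3D regions of at least `minVoxels` voxels
#' in each stack and returns one centroid per region. Multiple fields of view
#' are pooled.
#'
#' @param stacks an [ImageStack-class] or a list of them.
#' @param threshold intensity threshold.
#' @param minVoxels minimum region size in voxels (suppresses hot pixels).
#' @return data.frame with `stack`, `x_um`, `y_um`, `z_um`.
#' @export
detectNuclei <- function(stacks, threshold, minVoxels = 4L) {
  if (is(stacks, "ImageStack")) stacks <- list(stacks)
  out <- lapply(seq_along(stacks), function(s) {
    beads <- detectBeads(stacks[[s]], threshold, minSeparation = 0,
                         minVoxels = minVoxels)
    p <- positions(beads)
    if (nrow(p) == 0)
      return(data.frame(stack = integer(0), x_um = numeric(0),
                        y_um = numeric(0), z_um = numeric(0)))
    data.frame(stack = s, x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  })
  do.call(rbind, out)
}

#' Invasion-depth profile
#'
#' Converts nucleus z-positions into depths below the gel surface and builds
#' the cumulative invasion profile: the fraction of cells lying at or below
#' each depth. Cells above the surface (optical artifacts) are clamped to
#' depth 0. When no surface is supplied it is estimated as the mode of the
#' shallowest decile of the z-positions, since most non-invading cells sit on
#' the surface where they were seeded; z is taken to increase into the gel.
#'
#' @param nucleiZ numeric vector of nucleus z-positions, um.
#' @param surfaceZ gel surface z in um, or NULL to estimate it.
#' @param binWidth histogram bin width for the surface-mode estimate, um
#'   (default 2, the z-section interval).
#' @return an [InvasionProfile-class]
#' @export
invasionProfile <- function(nucleiZ, surfaceZ = NULL, binWidth = 2) {
  nucleiZ <- as.numeric(nucleiZ)
  if (length(nucleiZ) < 1L) stop("need at least one cell")
  if (is.null(surfaceZ)) {
    shallow <- nucleiZ[nucleiZ <= quantile(nucleiZ, 0.1)]
    if (length(shallow) < 1L) shallow <- min(nucleiZ)
    breaks <- seq(min(shallow) - binWidth, max(shallow) + binWidth,
                  by = binWidth)
    h <- hist(shallow, breaks = breaks, plot = FALSE)
    surfaceZ <- h$mids[which.max(h$counts)]
  }
  depths <- pmax(nucleiZ - surfaceZ, 0)
  new("InvasionProfile", depths = sort(depths), surfaceZ = surfaceZ,
      nCells = length(depths))
}

#' Evaluate an invasion profile
#'
#' The cumulative probability of finding a cell at or below each queried
#' depth: `P(depth >= d)`, a right-continuous non-increasing step function
#' with value 1 at depth 0.
#'
#' @param profile an [InvasionProfile-class].
#' @param depth numeric vector of query depths, um.
#' @return numeric vector of probabilities.
#' @export
profileProbability <- function(profile, depth) {
  stopifnot(is(profile, "InvasionProfile"))
  vapply(depth, function(d) mean(profile@depths >= d), numeric(1))
}

#' Invasion profile as a two-column table
#'
#' @param profile an [InvasionProfile-class].
#' @return data.frame with `depth_um` (the sorted unique depths, prefixed
#'   with 0) and `cum_prob`.
#' @export
profileTable <- function(profile) {
  d <- unique(c(0, profile@depths))
  data.frame(depth_um = d, cum_prob = profileProbability(profile, d))
}

#' @importFrom graphics hist
NULL
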