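# Bead detection and sub-voxel displacement tracking.

#' Detect beads in a 3D stack
#'
#' Thresholds the stack, labels connected above-threshold regions
#' (26-connectivity), and returns the intensity-weighted centroid of each
#' region in physical um coordinates. Detections closer than `minSeparation`
#' are de-duplicated by keeping the brighter (higher peak intensity) region.
#'
#' @param stack an [ImageStack-class].
#' @param threshold intensity threshold; voxels strictly above it belong to a
#'   bead region.
#' @param minSeparation minimum center-to-center distance in um (0 disables
#'   de-duplication).
#' @param minVoxels discard regions smaller than this many voxels (default 1).
#' @return a [BeadSet-class]
#' @export
detectBeads <- function(stack, threshold, minSeparation = 0, minVoxels = 1L) {
  stopifnot(is(stack, "ImageStack"), minSeparation >= 0)
  lab <- .cpp_label3d(as.numeric(stack@voxels), dim(stack@voxels), threshold)
  keep <- lab$n_voxels >= minVoxels
  if (!any(keep))
    return(BeadSet(matrix(numeric(0), ncol = 3), sourceStack = ""))
  # voxel-center coordinates -> physical um
  cen <- lab$centroid_vox[keep, , drop = FALSE]
  peak <- lab$peak_intensity[keep]
  pos <- sweep(sweep(cen + 0.5, 2, stack@spacing, "*"), 2, stack@origin, "+")

  if (minSeparation > 0 && nrow(pos) > 1) {
    ord <- order(peak, decreasing = TRUE)   # brighter beads claim space first
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0L) { kept <- i; next }
      d2 <- (pos[kept, 1] - pos[i, 1])^2 + (pos[kept, 2] - pos[i, 2])^2 +
            (pos[kept, 3] - pos[i, 3])^2
      if (all(d2 >= minSeparation^2)) kept <- c(kept, i)
    }
    pos <- pos[sort(kept), , drop = FALSE]
  }
  BeadSet(pos)
}

#' Track one bead between two stacks
#'
#' Cuts a subvolume around the bead out of the reference stack and shifts it
#' relative to the target stack until the sum of squared intensity
#' differences (SSD) is minimal; sub-voxel resolution comes from tri-linear
#' interpolation of the target intensities. Both subvolumes are
#' mean-subtracted before differencing, for robustness against bleaching.
#' The optimizer is a coarse integer-voxel grid search over the search radius
#' followed by a pattern search with successive step halving; the shift is
#' split symmetrically between the two stacks so both windows see the same
#' interpolation smoothing at the optimum. Both stacks are band-limited with
#' a small Gaussian (`presmoothSigma`) before matching, which suppresses the
#' sub-voxel bias ("peak locking") of tri-linear interpolation.
#'
#' @param refStack,targetStack [ImageStack-class] pair (relaxed / deformed);
#'   both must share the same voxel spacing.
#' @param refPosition numeric(3) bead position in the reference stack, um.
#' @param subvolumeSize numeric(3) subvolume edge lengths in um; default
#'   `c(4.5, 4.5, 14)` (x, y, z).
#' @param searchRadius maximum displacement searched, um (default 10).
#' @param presmoothSigma numeric(3) Gaussian pre-filter SDs in um (default
#'   `c(0.7, 0.7, 1.5)`, about one voxel per axis; 0 disables).
#' @return list with `displacement` (um, target minus reference), `residual`
#'   (SSD at the optimum), and `lost` (TRUE when the optimum hit the search
#'   boundary or the subvolume left either stack).
#' @export
trackBead <- function(refStack, targetStack, refPosition,
                      subvolumeSize = c(4.5, 4.5, 14.0), searchRadius = 10,
                      presmoothSigma = c(0.7, 0.7, 1.5)) {
  res <- trackAll(refStack, targetStack,
                  BeadSet(matrix(refPosition, ncol = 3)),
                  subvolumeSize = subvolumeSize, searchRadius = searchRadius,
                  presmoothSigma = presmoothSigma, minTrackable = 0L)
  list(displacement = as.numeric(displacements(res)[1, ]),
       residual = matchResiduals(res)[1], lost = lostMask(res)[1])
}

#' Sub-voxel tracking accuracy on synthetic shifts
#'
#' Renders a single 1 um bead into a reference stack, applies seeded
#' uniformly random sub-voxel 3D shifts (each up to one voxel per axis),
#' renders the shifted stacks, tracks the bead back with [trackBead()], and
#' reports the RMS errors against the known shifts. This reproduces the
#' standard accuracy protocol for the difference-with-interpolation tracker
#' at the reference acquisition geometry.
#'
#' @param nShifts number of random shifts (default 100).
#' @param spacing voxel pitch, um.
#' @param psfSigma rendered PSF sigmas, um.
#' @param intensity peak bead intensity.
#' @param searchRadius tracking search radius, um.
#' @param seed RNG seed for the shifts.
#' @return list with `lateral_rms_nm`, `axial_rms_nm`, and the n x 3 matrix
#'   of `errors_um`.
#' @export
trackerAccuracy <- function(nShifts = 100, spacing = c(0.645, 0.645, 2.0),
                            psfSigma = c(0.4, 0.4, 1.5), intensity = 1000,
                            searchRadius = 3, seed = 1) {
  box <- spacing * c(31, 31, 17)
  center <- box / 2
  shifts <- .withSeed(seed, matrix(runif(3 * nShifts, -1, 1), ncol = 3,
                                   byrow = TRUE) *
                              matrix(spacing, nShifts, 3, byrow = TRUE))
  ref <- renderStack(matrix(center, ncol = 3), box, spacing, psfSigma,
                     intensity)
  err <- matrix(0, nShifts, 3)
  for (i in seq_len(nShifts)) {
    tar <- renderStack(matrix(center + shifts[i, ], ncol = 3), box, spacing,
                       psfSigma, intensity)
    r <- trackBead(ref, tar, center, searchRadius = searchRadius)
    err[i, ] <- r$displacement - shifts[i, ]
  }
  list(lateral_rms_nm = 1000 * sqrt(mean(err[, 1:2]^2)),
       axial_rms_nm = 1000 * sqrt(mean(err[, 3]^2)),
       errors_um = err)
}

#' Track all beads between two stacks
#'
#' Applies the subvolume SSD matcher (see [trackBead()]) to every bead.
#' Beads whose subvolume leaves a stack or whose optimum sits on the search
#' boundary are flagged lost, never dropped silently. Optionally a global
#' stage-drift correction is applied by subtracting the median displacement
#' of the 10% of beads farthest from `cellCenter`; whether it was applied is
#' recorded in the result's provenance.
#'
#' @inheritParams trackBead
#' @param beads a [BeadSet-class] detected in the reference stack.
#' @param driftCorrect logical, default FALSE.
#' @param cellCenter numeric(3) used to pick far-field beads for drift
#'   estimation (defaults to the bead centroid).
#' @param minTrackable raise an error if fewer beads remain trackable
#'   (default 5, the minimum for a non-degenerate mesh).
#' @return a [MatchedDisplacements-class]
#' @export
trackAll <- function(refStack, targetStack, beads,
                     subvolumeSize = c(4.5, 4.5, 14.0), searchRadius = 10,
                     presmoothSigma = c(0.7, 0.7, 1.5), driftCorrect = FALSE,
                     cellCenter = NULL, minTrackable = 5L) {
  stopifnot(is(refStack, "ImageStack"), is(targetStack, "ImageStack"),
            is(beads, "BeadSet"), searchRadius > 0)
  if (max(abs(refStack@spacing - targetStack@spacing)) > 1e-9)
    stop("reference and target stacks must share voxel spacing")
  pos <- positions(beads)
  refVox <- as.numeric(refStack@voxels)
  tarVox <- as.numeric(targetStack@voxels)
  if (any(presmoothSigma > 0)) {
    refVox <- .cpp_gauss3d(refVox, dim(refStack@voxels),
                           presmoothSigma / refStack@spacing)
    tarVox <- .cpp_gauss3d(tarVox, dim(targetStack@voxels),
                           presmoothSigma / targetStack@spacing)
  }
  res <- .cpp_track(refVox, dim(refStack@voxels),
                    tarVox, dim(targetStack@voxels),
                    pos, refStack@spacing, refStack@origin,
                    targetStack@origin, as.numeric(subvolumeSize),
                    searchRadius)
  disp <- res$displacements
  lost <- as.logical(res$lost)
  if (sum(!lost) < minTrackable)
    stop(sprintf("only %d beads trackable (need >= %d)", sum(!lost),
                 minTrackable))
  drift <- c(0, 0, 0)
  if (driftCorrect && any(!lost)) {
    if (is.null(cellCenter)) cellCenter <- colMeans(pos)
    d <- sqrt(rowSums(sweep(pos, 2, cellCenter)^2))
    far <- !lost & d >= quantile(d[!lost], 0.9)
    if (!any(far)) far <- !lost
    drift <- apply(disp[far, , drop = FALSE], 2, median)
    disp <- sweep(disp, 2, drift)
  }
  colnames(disp) <- c("ux", "uy", "uz")
  new("MatchedDisplacements", refPositions = pos, displacements = disp,
      residuals = as.numeric(res$residuals), lost = lost,
      provenance = list(subvolume_um = subvolumeSize,
                        search_radius_um = searchRadius,
                        presmooth_sigma_um = presmoothSigma,
                        drift_corrected = driftCorrect,
                        drift_um = drift))
}
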