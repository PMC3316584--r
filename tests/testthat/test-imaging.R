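# Bead detection and sub-voxel tracking.

test_that("a symmetric blob is detected at its center; empty stacks give no beads", {
  box <- c(100, 100, 200)
  st <- renderStack(matrix(c(50, 50, 100), ncol = 3), box, REF_SPACING)
  beads <- detectBeads(st, 0.5 * max(voxels(st)))
  expect_equal(length(beads), 1L)
  expect_true(all(abs(positions(beads) - c(50, 50, 100)) <= REF_SPACING))

  empty <- ImageStack(array(0, c(20, 20, 10)), REF_SPACING)
  expect_equal(length(detectBeads(empty, 0.1)), 0L)
})

test_that("a seeded field of non-overlapping blobs is fully recovered", {
  box <- c(150, 150, 150)
  pos <- sampleBeads(box, meanSpacing = 15, minSeparation = 8, seed = 21)
  inner <- pos[apply(pos, 1, function(p) all(p > 6 & p < box - 6)), ]
  st <- renderStack(inner, box, REF_SPACING)
  beads <- detectBeads(st, 0.3 * max(voxels(st)), minSeparation = 3)
  expect_equal(length(beads), nrow(inner))
  # match each detection to its nearest truth: all within one voxel
  d <- as.matrix(dist(rbind(positions(beads), inner)))
  n <- nrow(inner)
  nearest <- apply(d[seq_len(n), n + seq_len(n), drop = FALSE], 1, min)
  expect_lt(max(nearest), max(REF_SPACING))
})

test_that("near-duplicate detections keep the brighter region", {
  box <- c(40, 40, 40)
  pos <- rbind(c(18, 20, 20), c(23, 20, 20))
  st1 <- renderStack(pos[1, , drop = FALSE], box, REF_SPACING, intensity = 2000)
  st2 <- renderStack(pos[2, , drop = FALSE], box, REF_SPACING, intensity = 800)
  st <- ImageStack(voxels(st1) + voxels(st2), REF_SPACING)
  beads <- detectBeads(st, 200, minSeparation = 10)
  expect_equal(length(beads), 1L)
  expect_lt(abs(positions(beads)[1, 1] - 18), 1.5)
})

test_that("self-tracking returns exactly zero displacement and residual", {
  box <- c(40, 40, 80)
  st <- renderStack(matrix(c(20, 20, 40), ncol = 3), box, REF_SPACING)
  r <- trackBead(st, st, c(20, 20, 40), searchRadius = 5)
  expect_identical(r$displacement, c(0, 0, 0))
  expect_identical(r$residual, 0)
  expect_false(r$lost)
})

test_that("integer-voxel shifts are recovered exactly", {
  box <- c(40, 40, 80)
  ctr <- c(20, 20, 40)
  ref <- renderStack(matrix(ctr, ncol = 3), box, REF_SPACING)
  # shift the image grid content by one voxel in x via the rendered position
  tar <- renderStack(matrix(ctr + c(REF_SPACING[1], 0, 0), ncol = 3), box,
                     REF_SPACING)
  r <- trackBead(ref, tar, ctr, searchRadius = 3)
  expect_equal(r$displacement, c(REF_SPACING[1], 0, 0), tolerance = 1e-4)
})

test_that("tracking is equivariant under a common integer-voxel origin shift", {
  box <- c(40, 40, 80)
  ctr <- c(20, 20, 40)
  shift <- c(0.21, -0.33, 0.6)
  ref <- renderStack(matrix(ctr, ncol = 3), box, REF_SPACING)
  tar <- renderStack(matrix(ctr + shift, ncol = 3), box, REF_SPACING)
  r1 <- trackBead(ref, tar, ctr, searchRadius = 3)
  off <- REF_SPACING * c(2, 1, 1)   # whole voxels
  ref2 <- ImageStack(voxels(ref), REF_SPACING, origin = off)
  tar2 <- ImageStack(voxels(tar), REF_SPACING, origin = off)
  r2 <- trackBead(ref2, tar2, ctr + off, searchRadius = 3)
  expect_equal(r1$displacement, r2$displacement, tolerance = 1e-9)
})

test_that("track_all recovers a rigid sub-voxel translation for every bead", {
  box <- c(120, 120, 120)
  pos <- sampleBeads(box, meanSpacing = 20, minSeparation = 10, seed = 31)
  inner <- pos[apply(pos, 1, function(p) all(p > 15 & p < box[1] - 15)), ]
  shift <- c(0.3, 0.3, 0.6) * REF_SPACING   # 0.3 voxel in each direction
  ref <- renderStack(inner, box, REF_SPACING)
  tar <- renderStack(sweep(inner, 2, shift, "+"), box, REF_SPACING)
  res <- trackAll(ref, tar, BeadSet(inner), searchRadius = 3)
  expect_false(any(lostMask(res)))
  err <- sweep(displacements(res), 2, shift)
  expect_lt(sqrt(mean(err[, 1:2]^2)), 0.022)
  expect_lt(sqrt(mean(err[, 3]^2)), 0.130)

  # identical stacks: every displacement is exactly zero
  res0 <- trackAll(ref, ref, BeadSet(inner), searchRadius = 3)
  expect_equal(max(abs(displacements(res0))), 0)
  expect_false(any(lostMask(res0)))
})

test_that("beads near the boundary or outside the search range are flagged lost", {
  box <- c(60, 60, 60)
  ctr <- c(30, 30, 30)
  ref <- renderStack(matrix(ctr, ncol = 3), box, REF_SPACING)
  edge <- renderStack(matrix(c(2, 30, 30), ncol = 3), box, REF_SPACING)
  r <- trackBead(ref, ref, c(2, 30, 30))   # subvolume exits the stack
  expect_true(r$lost)
  # bead moved beyond the search radius: optimum pinned to the boundary
  far <- renderStack(matrix(ctr + c(8, 0, 0), ncol = 3), box, REF_SPACING)
  r2 <- trackBead(ref, far, ctr, searchRadius = 3)
  expect_true(r2$lost)
  expect_error(trackAll(ref, ref, BeadSet(matrix(c(2, 30, 30), ncol = 3))),
               "trackable")
})

test_that("far-field drift correction removes a stage offset", {
  box <- c(120, 120, 120)
  pos <- sampleBeads(box, meanSpacing = 22, minSeparation = 10, seed = 37)
  inner <- pos[apply(pos, 1, function(p) all(p > 15 & p < box[1] - 15)), ]
  drift <- c(0.2, -0.1, 0.4)
  ref <- renderStack(inner, box, REF_SPACING)
  tar <- renderStack(sweep(inner, 2, drift, "+"), box, REF_SPACING)
  res <- trackAll(ref, tar, BeadSet(inner), searchRadius = 3,
                  driftCorrect = TRUE)
  expect_lt(max(abs(displacements(res)[!lostMask(res), ])), 0.05)
  expect_true(res@provenance$drift_corrected)
  expect_lt(max(abs(res@provenance$drift_um - drift)), 0.13)
})
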