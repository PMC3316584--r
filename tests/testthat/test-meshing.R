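# Delaunay tessellation and tetrahedron shape quality.

test_that("shape factor hits its endpoints and is geometry-invariant", {
  expect_equal(shapeQuality(regularTet(1)), 1)
  expect_equal(shapeQuality(regularTet(7.3)), 1)
  expect_equal(shapeQuality(flatTet()), 0)

  set.seed(1)
  for (i in 1:20) {
    tet <- matrix(rnorm(12, sd = 5), 4, 3)
    q <- shapeQuality(tet)
    expect_gte(q, 0)
    expect_lte(q, 1)
    # uniform scaling
    expect_equal(shapeQuality(tet * 10), q, tolerance = 1e-12)
    # rotation + translation
    R <- rotationMatrix(runif(1, 0, 2 * pi), rnorm(3))
    moved <- tet %*% t(R) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(shapeQuality(moved), q, tolerance = 1e-9)
    # vertex permutation
    expect_equal(shapeQuality(tet[sample(4), ]), q, tolerance = 1e-12)
  }
  expect_error(shapeQuality(matrix(1, 4, 3)), "identical")
})

test_that("tessellation conserves hull volume and uses every node", {
  pts <- boxCloud(n = 200, side = 1)
  mesh <- suppressWarnings(tessellate(pts, qMin = 0))
  expect_equal(sum(volumes(mesh)), 1, tolerance = 1e-9)
  expect_true(all(seq_len(nrow(pts)) %in% as.vector(elements(mesh))))
  expect_true(all(apply(elements(mesh), 1, anyDuplicated) == 0))

  pts2 <- boxCloud(n = 1000, side = 300, seed = 7)
  mesh2 <- suppressWarnings(tessellate(pts2, qMin = 0))
  expect_equal(sum(volumes(mesh2)) / 300^3, 1, tolerance = 1e-6)
})

test_that("five points (regular tet + centroid) give 4 elements around the centroid", {
  p5 <- rbind(regularTet(1), c(0, 0, 0))
  mesh <- suppressWarnings(tessellate(p5, qMin = 0))
  expect_equal(nrow(elements(mesh)), 4L)
  expect_true(all(apply(elements(mesh), 1, function(r) 5L %in% r)))
})

test_that("degenerate point sets are rejected", {
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(tessellate(flat), "coplanar")
  expect_error(tessellate(matrix(runif(9), 3, 3)), "at least 5")
})

test_that("the empty-circumsphere property holds against brute force", {
  for (seed in c(3, 7)) {
    set.seed(seed)
    pts <- matrix(runif(3 * 30, 0, 10), ncol = 3)
    mesh <- suppressWarnings(tessellate(pts, qMin = 0))
    expect_lt(worstCircumsphereViolation(pts, elements(mesh)), 1e-6)
  }
})

test_that("quality filter thresholds with the boundary kept", {
  pts <- boxCloud(n = 100, side = 50, seed = 11)
  mesh <- suppressWarnings(tessellate(pts, qMin = 0))
  q <- quality(mesh)
  # brute-force recomputation per element
  qref <- vapply(seq_len(nrow(elements(mesh))), function(e)
    shapeQuality(pts[elements(mesh)[e, ], ]), numeric(1))
  expect_equal(q, qref, tolerance = 1e-12)

  f <- suppressWarnings(filterByQuality(mesh, 0.5))
  expect_equal(validMask(f), q >= 0.5)
  expect_identical(nodes(f), nodes(mesh))
  all_valid <- filterByQuality(mesh, 0)
  expect_true(all(validMask(all_valid)))

  # exact-boundary semantics on a synthetic quality vector
  m2 <- mesh
  m2@quality <- rep(c(0.2, 0.5, 0.9), length.out = length(q))
  f2 <- suppressWarnings(filterByQuality(m2, 0.5))
  expect_equal(validMask(f2), m2@quality >= 0.5)
  expect_warning(filterByQuality(m2, 0.95), "excluded")
})

test_that("mesh export and element table round the same data", {
  pts <- boxCloud(n = 30, side = 20, seed = 5)
  mesh <- suppressWarnings(tessellate(pts))
  tab <- meshElementTable(mesh)
  expect_equal(nrow(tab), nrow(elements(mesh)))
  expect_equal(tab$volume_um3, volumes(mesh))
  vtk <- tempfile(fileext = ".vtk")
  writeMeshVTK(mesh, vtk)
  lines <- readLines(vtk)
  expect_true(any(grepl("^POINTS", lines)))
  expect_equal(sum(grepl("^SCALARS", lines)), 2L)
})
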