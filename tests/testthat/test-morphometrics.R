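# Anisotropy indices, focus selection, log-normal summaries.

ngon <- function(r, n = 64, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("a circular contour scores anisotropy 1; an ellipse scores (a/b)^2", {
  circ <- shapeAnisotropy(ngon(20), rasterSpacing = 0.645)
  expect_equal(anisotropyIndex(circ), 1, tolerance = 1e-2)

  ell <- ngon(1)
  ell[, 1] <- ell[, 1] * 40
  ell[, 2] <- ell[, 2] * 20
  # solid-ellipse second moments scale as the squared axes
  res <- shapeAnisotropy(ell, rasterSpacing = 0.645)
  expect_equal(anisotropyIndex(res), 4, tolerance = 0.02 * 4)
})

test_that("the shape index is invariant under rotation, translation and scale", {
  set.seed(8)
  blob <- ngon(1, 32) * runif(32, 15, 30)   # irregular star-ish polygon
  base <- anisotropyIndex(shapeAnisotropy(blob, 0.3))
  R <- rotationMatrix(37 * pi / 180)[1:2, 1:2]
  rot <- blob %*% t(R)
  expect_equal(anisotropyIndex(shapeAnisotropy(rot, 0.3)), base,
               tolerance = 1e-2)
  moved <- sweep(blob * 2, 2, c(100, -50), "+")
  expect_equal(anisotropyIndex(shapeAnisotropy(moved, 0.6)), base,
               tolerance = 1e-2)
  # raster-resolution convergence: halving the spacing moves the index < 1%
  fine <- anisotropyIndex(shapeAnisotropy(blob, 0.15))
  expect_equal(fine / base, 1, tolerance = 0.01)
  expect_error(shapeAnisotropy(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("energy anisotropy is 1 for isotropic fields and large for dipoles", {
  set.seed(12)
  n <- 5000
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  r <- runif(n, 10, 60)
  iso <- pointAnisotropy(dirs * r, weights = 1 / r^2)
  expect_equal(anisotropyIndex(iso), 1, tolerance = 0.05)

  # two antipodal energy clusters: index >> 1, growing with separation
  pole <- function(sep) {
    pts <- rbind(matrix(rnorm(300, sd = 3), ncol = 3) +
                   matrix(c(sep / 2, 0, 0), 100, 3, byrow = TRUE),
                 matrix(rnorm(300, sd = 3), ncol = 3) -
                   matrix(c(sep / 2, 0, 0), 100, 3, byrow = TRUE))
    anisotropyIndex(pointAnisotropy(pts, rep(1, 200)))
  }
  a30 <- pole(30); a60 <- pole(60)
  expect_gt(a30, 5)
  expect_gt(a60, a30)
})

test_that("energy anisotropy of an assembled field is rotation-invariant", {
  mat <- ElasticMaterial(118, 0.35)
  sc <- dipoleScene(box = c(150, 150, 150), separation = 40, cellRadius = 12,
                    seed = 6, computeAnalytic = FALSE)
  mesh <- suppressWarnings(tessellate(sc@positions))
  f <- assembleField(mesh, sc@manifest$displacements, mat,
                     NoiseModel(c(0, 0, 0)))
  a1 <- energyAnisotropy(f)
  expect_gt(anisotropyIndex(a1), 1.5)   # elongated source
  # rigid rotation of the whole scene
  R <- rotationMatrix(0.7, c(0, 1, 1))
  ctr <- sc@params$center
  rot <- function(x) sweep(sweep(x, 2, ctr) %*% t(R), 2, ctr, "+")
  mesh2 <- mesh
  mesh2@nodes <- rot(mesh@nodes)
  u2 <- sc@manifest$displacements %*% t(R)
  f2 <- assembleField(mesh2, u2, mat, NoiseModel(c(0, 0, 0)))
  expect_equal(anisotropyIndex(energyAnisotropy(f2)), anisotropyIndex(a1),
               tolerance = 1e-6)
})

test_that("the focus measure picks the sharp slice, with low-z tie-breaking", {
  set.seed(14)
  sharp <- matrix(as.numeric(runif(1600) > 0.5), 40, 40)
  blurry <- matrix(0.5, 40, 40)
  vox <- array(0, c(40, 40, 5))
  for (k in 1:5) vox[, , k] <- blurry + 0.02 * matrix(rnorm(1600), 40)
  vox[, , 3] <- sharp
  st <- ImageStack(vox, REF_SPACING)
  expect_equal(focusPlane(st), 3L)
  uni <- ImageStack(array(1, c(20, 20, 6)), REF_SPACING)
  expect_equal(focusPlane(uni), 1L)
  # roi restriction: sharpness only inside the roi counts
  vox2 <- array(0, c(40, 40, 5))
  vox2[1:20, , 2] <- sharp[1:20, ]
  vox2[21:40, , 4] <- sharp[21:40, ]
  st2 <- ImageStack(vox2, c(1, 1, 2))
  expect_equal(focusPlane(st2, roi = c(0, 19, 0, 40)), 2L)
  expect_equal(focusPlane(st2, roi = c(21, 40, 0, 40)), 4L)
})

test_that("geometric summaries match closed forms and recover log-normal parameters", {
  s <- geometricSummary(c(10, 10, 10))
  expect_equal(s$geometric_mean, 10)
  expect_equal(s$geometric_se, 1)
  expect_equal(geometricSummary(c(1, 100))$geometric_mean, 10)
  expect_error(geometricSummary(c(1, -2, 3)), "positive")
  expect_error(geometricSummary(5), "at least 2")

  set.seed(16)
  x <- exp(rnorm(1e4, meanlog <- 1.3, sdlog <- 0.6))
  fit <- geometricSummary(x)
  se <- sdlog / sqrt(1e4)
  expect_lt(abs(fit$meanlog - meanlog), 3 * se)
  expect_lt(abs(fit$sdlog - sdlog), 3 * se)
  expect_equal(fit$geometric_mean, exp(fit$meanlog))
})
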