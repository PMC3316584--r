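# Ground-truth scene generation: bead sampling, analytic fields, rendering.

mat <- ElasticMaterial(118, 0.35)

test_that("bead sampling hits the target density, separation and determinism", {
  pos <- sampleBeads(c(240, 240, 240), meanSpacing = 24, seed = 5)
  expect_equal(nrow(pos), 1000, tolerance = 0.1)
  expect_gte(min(dist(pos[1:300, ])), 4)
  pos2 <- sampleBeads(c(240, 240, 240), meanSpacing = 24, seed = 5)
  expect_identical(pos, pos2)
  expect_true(all(pos >= 0 & pos <= 240))
  expect_error(sampleBeads(c(50, 50, 50), meanSpacing = 10,
                           minSeparation = 9.9), "infeasible")
})

test_that("the point-force field decays as 1/r and is odd in the force", {
  F <- c(0, 0, 5e-8)
  u1 <- kelvinDisplacement(matrix(c(10, 0, 0), ncol = 3), F, c(0, 0, 0), mat)
  u2 <- kelvinDisplacement(matrix(c(20, 0, 0), ncol = 3), F, c(0, 0, 0), mat)
  expect_equal(sqrt(sum(u1^2)) / sqrt(sum(u2^2)), 2, tolerance = 1e-12)
  # on-axis displacement is parallel to F; sign flips with the force
  on <- kelvinDisplacement(matrix(c(0, 0, 30), ncol = 3), F, c(0, 0, 0), mat)
  expect_equal(on[1:2], c(0, 0))
  expect_gt(on[3], 0)
  neg <- kelvinDisplacement(matrix(c(0, 0, 30), ncol = 3), -F, c(0, 0, 0), mat)
  expect_equal(neg, -on)
  expect_error(kelvinDisplacement(matrix(c(0, 0, 0), ncol = 3), F, c(0, 0, 0),
                                  mat), "coincides")
})

test_that("the point-force field satisfies elastic equilibrium away from the origin", {
  # finite-difference divergence of the stress tensor on a small grid
  F <- c(1e-8, -2e-8, 1.5e-8)
  G <- shearModulus(mat); lam <- lameLambda(mat)
  stressAt <- function(p) {
    g <- matrix(tfm3d:::.kelvinGradient(matrix(p, ncol = 3), F, c(0, 0, 0),
                                        mat), 3, 3)
    eps <- (g + t(g)) / 2
    lam * sum(diag(eps)) * diag(3) + 2 * G * eps
  }
  h <- 1e-3
  for (p0 in list(c(14, 3, -6), c(-8, 11, 5))) {
    divs <- numeric(3)
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      divs <- divs + (stressAt(p0 + e) - stressAt(p0 - e))[, k] / (2 * h)
    }
    # central differences at h = 1e-3: truncation ~ h^2 relative
    expect_lt(max(abs(divs)), 1e-5 * max(abs(stressAt(p0))))
  }
})

test_that("the dipole field is mirror-symmetric, contractile, and linear in the force", {
  ax <- c(1, 0, 0)
  ctr <- c(0, 0, 0)
  p <- matrix(c(40, 7, -3), ncol = 3)
  pm <- p; pm[, 1] <- -pm[, 1]
  u <- dipoleDisplacement(p, 2e-8, ax, 30, ctr, mat)
  um <- dipoleDisplacement(pm, 2e-8, ax, 30, ctr, mat)
  expect_equal(u[, 1], -um[, 1], tolerance = 1e-12)
  expect_equal(u[, 2:3], um[, 2:3], tolerance = 1e-12)
  # on-axis points outside the poles move toward the center (contraction)
  expect_lt(u[1, 1], 0)
  expect_equal(dipoleDisplacement(p, 4e-8, ax, 30, ctr, mat), 2 * u,
               tolerance = 1e-12)
  # energy density is quadratic in the force magnitude
  w1 <- dipoleEnergyDensity(p, 2e-8, ax, 30, ctr, mat)
  w2 <- dipoleEnergyDensity(p, 4e-8, ax, 30, ctr, mat)
  expect_equal(w2, 4 * w1, tolerance = 1e-12)
})

test_that("affine fields are exact: translations are energy-free, strains uniform", {
  pts <- boxCloud(n = 100, side = 80, seed = 41)
  mesh <- suppressWarnings(tessellate(pts))
  ut <- affineDisplacement(pts, translation = c(2, -1, 3))
  f <- assembleField(mesh, ut, mat, NoiseModel(c(0, 0, 0)))
  expect_lt(sum(rawEnergy(f)), 1e-12)
  # 1% uniaxial stretch: uniform density over computed elements
  us <- affineDisplacement(pts, strain = diag(c(0.01, 0, 0)))
  fs <- assembleField(mesh, us, mat, NoiseModel(c(0, 0, 0)))
  w <- energyDensity(fs)[validMask(mesh)]
  expect_equal(max(w) / min(w), 1, tolerance = 1e-9)
  expect_equal(w[1], continuumEnergyDensity(diag(c(0.01, 0, 0)), mat),
               tolerance = 1e-9)
})

test_that("rendering places blob maxima on the right voxels, deterministically", {
  box <- c(30, 30, 60)
  p <- matrix(c(13.1, 17.8, 31.2), ncol = 3)
  st <- renderStack(p, box, REF_SPACING)
  idx <- arrayInd(which.max(voxels(st)), dim(st))
  vc <- (idx - 0.5) * REF_SPACING
  expect_true(all(abs(vc - p) <= REF_SPACING / 2 + 1e-9))
  st2 <- renderStack(p, box, REF_SPACING)
  expect_identical(voxels(st), voxels(st2))
  # seeded noise is reproducible and changes with the seed
  n1 <- renderStack(p, box, REF_SPACING, noise = "poisson", seed = 3)
  n2 <- renderStack(p, box, REF_SPACING, noise = "poisson", seed = 3)
  n3 <- renderStack(p, box, REF_SPACING, noise = "poisson", seed = 4)
  expect_identical(voxels(n1), voxels(n2))
  expect_false(identical(voxels(n1), voxels(n3)))
})

test_that("the dipole scene manifest matches the model at the bead positions", {
  sc <- dipoleScene(box = c(120, 120, 120), separation = 30, cellRadius = 10,
                    seed = 2, computeAnalytic = FALSE)
  u <- dipoleDisplacement(sc@positions, sc@params$magnitude_N, sc@params$axis,
                          sc@params$separation_um, sc@params$center,
                          sc@material)
  expect_equal(sc@manifest$displacements, u, tolerance = 1e-12)
  # no beads inside the cell capsule
  expect_gt(min(tfm3d:::.distToSegment(
    sc@positions,
    sc@params$center - sc@params$axis * sc@params$separation_um / 2,
    sc@params$center + sc@params$axis * sc@params$separation_um / 2)),
    sc@params$cell_radius_um)
  sc2 <- dipoleScene(box = c(120, 120, 120), separation = 30, cellRadius = 10,
                     seed = 2, computeAnalytic = FALSE)
  expect_identical(sc@positions, sc2@positions)
})

test_that("the analytic-energy quadratures converge on themselves", {
  # quadrature orders well beyond the defaults must not move the result
  e1 <- dipoleFieldEnergy(1.5e-8, c(1, 0, 0), 50, c(0, 0, 0), mat,
                          shell = c(40, 90))
  e2 <- dipoleFieldEnergy(1.5e-8, c(1, 0, 0), 50, c(0, 0, 0), mat,
                          shell = c(40, 90), nr = 96, ntheta = 64, nphi = 128)
  expect_equal(e1 / e2, 1, tolerance = 1e-6)
  # and the tetrahedron rule integrates a far-field tet consistently
  v <- regularTet(12) + matrix(c(80, 0, 0), 4, 3, byrow = TRUE)
  q2 <- tfm3d:::.integrateOverTets(function(p)
    dipoleEnergyDensity(p, 1.5e-8, c(1, 0, 0), 50, c(0, 0, 0), mat),
    v, matrix(1:4, 1), depth = 2)
  q4 <- tfm3d:::.integrateOverTets(function(p)
    dipoleEnergyDensity(p, 1.5e-8, c(1, 0, 0), 50, c(0, 0, 0), mat),
    v, matrix(1:4, 1), depth = 4)
  expect_equal(q2 / q4, 1, tolerance = 1e-4)
})
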