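# Linear tetrahedral elasticity: stiffness, energies, noise baseline.

mat <- ElasticMaterial(118, 0.35)

test_that("element stiffness is symmetric PSD with a 6D rigid-body null space", {
  set.seed(2)
  for (i in 1:5) {
    tet <- matrix(rnorm(12, sd = 8), 4, 3)
    if (abs(det(cbind(1, tet))) < 1e-3) next
    K <- elementStiffness(tet, mat)
    expect_equal(max(abs(K - t(K))), 0)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
    expect_true(all(ev[1:6] > 0))
    # uniform translation lies in the null space
    expect_lt(max(abs(K %*% rep(c(1, 2, 3), 4))), 1e-9 * max(abs(K)))
  }
  expect_error(elementStiffness(flatTet(), mat), "zero-volume")
})

test_that("affine displacement fields reproduce the continuum energy density exactly", {
  tet <- regularTet(10)
  K <- elementStiffness(tet, mat)
  V <- abs(det(cbind(1, tet))) / 6
  lam <- lameLambda(mat)

  # 1% triaxial dilation: U = (9 lambda / 2 + 3 G) eps^2 V
  u <- affineDisplacement(tet, strain = diag(0.01, 3))
  expect_equal(elementEnergy(K, u),
               (9 * lam / 2 + 3 * 118) * 0.01^2 * V * 1e-6,
               tolerance = 1e-12)

  # random small strains against the closed form, on random elements too
  set.seed(4)
  for (i in 1:10) {
    S <- matrix(rnorm(9, sd = 0.01), 3)
    S <- (S + t(S)) / 2
    w <- continuumEnergyDensity(S, mat)
    tet2 <- matrix(rnorm(12, sd = 6), 4, 3)
    if (abs(det(cbind(1, tet2))) < 1e-2) next
    V2 <- abs(det(cbind(1, tet2))) / 6
    K2 <- elementStiffness(tet2, mat)
    u2 <- affineDisplacement(tet2, strain = S)
    expect_equal(elementEnergy(K2, u2), w * V2 * 1e-6, tolerance = 1e-9)
  }
})

test_that("rigid motions carry no energy; small rotations scale as theta^4", {
  tet <- regularTet(10)
  K <- elementStiffness(tet, mat)
  expect_equal(elementEnergy(K, rep(0, 12)), 0)
  expect_lt(elementEnergy(K, rep(c(5, -3, 2), 4)), 1e-15)
  u3 <- elementEnergy(K, affineDisplacement(tet, rotation = rotationMatrix(1e-3)))
  u2 <- elementEnergy(K, affineDisplacement(tet, rotation = rotationMatrix(1e-2)))
  expect_equal(u2 / u3, 1e4, tolerance = 0.01)
})

test_that("noise baseline equals the trace formula and scales with the covariance", {
  K <- elementStiffness(regularTet(12), mat)
  expect_equal(noiseBaseline(K, NoiseModel(c(0, 0, 0))), 0)
  b1 <- noiseBaseline(K, NoiseModel(c(0.022, 0.022, 0.130)))
  b2 <- noiseBaseline(K, NoiseModel(sqrt(2) * c(0.022, 0.022, 0.130)))
  expect_equal(b2, 2 * b1, tolerance = 1e-12)

  # Monte-Carlo oracle: mean of 1/2 n' K n over 1e5 draws
  set.seed(9)
  sig <- c(0.022, 0.022, 0.130)
  N <- matrix(rnorm(12 * 1e5, 0, rep(sig, 4)), nrow = 12)
  mc <- mean(colSums(N * (K %*% N)) / 2) * 1e-6
  expect_equal(b1, mc, tolerance = 0.01)
})

test_that("assembled fields honour the unit relation and the fill provenance", {
  pts <- boxCloud(n = 150, side = 120, seed = 13)
  mesh <- suppressWarnings(tessellate(pts))
  # zero displacements, zero noise -> all energies zero
  f0 <- assembleField(mesh, matrix(0, nrow(pts), 3), mat, NoiseModel(c(0, 0, 0)))
  expect_equal(sum(abs(rawEnergy(f0))), 0)
  expect_equal(sum(abs(correctedEnergy(f0))), 0)

  # affine field: per-element energies match direct recomputation
  u <- affineDisplacement(pts, strain = diag(c(0.01, -0.004, 0.006)))
  f <- assembleField(mesh, u, mat, NoiseModel(c(0, 0, 0)))
  el <- elements(mesh)
  for (e in sample(which(validMask(mesh)), 10)) {
    K <- elementStiffness(pts[el[e, ], ], mat)
    expect_equal(rawEnergy(f)[e],
                 elementEnergy(K, as.numeric(t(u[el[e, ], ]))),
                 tolerance = 1e-12)
  }
  # density * volume reproduces energy on computed elements (units Pa, um^3, pJ)
  v <- validMask(mesh)
  expect_equal(energyDensity(f)[v] * volumes(mesh)[v] * 1e-6,
               correctedEnergy(f)[v], tolerance = 1e-12)
  # filled elements point at a valid source carrying the same density
  if (any(f@filled)) {
    src <- f@fillSource[f@filled]
    expect_true(all(validMask(mesh)[src]))
    expect_equal(energyDensity(f)[f@filled], energyDensity(f)[src])
  }
  expect_error(assembleField(mesh, u[-1, ]), "1:1")
})

test_that("energy is invariant to uniform displacement offsets", {
  pts <- boxCloud(n = 80, side = 80, seed = 17)
  mesh <- suppressWarnings(tessellate(pts))
  u <- affineDisplacement(pts, strain = diag(0.008, 3))
  f1 <- assembleField(mesh, u, mat, NoiseModel(c(0, 0, 0)))
  f2 <- assembleField(mesh, sweep(u, 2, c(3, -1, 2), "+"), mat,
                      NoiseModel(c(0, 0, 0)))
  expect_equal(rawEnergy(f1), rawEnergy(f2), tolerance = 1e-8)
})

test_that("total energy accumulates element energies by centroid radius", {
  pts <- boxCloud(n = 120, side = 100, seed = 19)
  mesh <- suppressWarnings(tessellate(pts))
  u <- affineDisplacement(pts, strain = diag(0.01, 3))
  f <- assembleField(mesh, u, mat, NoiseModel(c(0, 0, 0)))
  te <- totalEnergy(f, c(50, 50, 50), radii = c(20, 40, Inf))
  expect_equal(te$plateau_pJ, sum(correctedEnergy(f)))
  cen <- elementCentroids(mesh)
  r <- sqrt(rowSums(sweep(cen, 2, c(50, 50, 50))^2))
  expect_equal(te$cumulative_pJ[1], sum(correctedEnergy(f)[r <= 20]))
  expect_true(!is.unsorted(te$radii_um))
})

test_that("relative change maps are zero for identical fields and +1 for doubled ones", {
  pts <- boxCloud(n = 100, side = 100, seed = 23)
  mesh <- suppressWarnings(tessellate(pts))
  u <- affineDisplacement(pts, strain = diag(0.01, 3))
  f1 <- assembleField(mesh, u, mat, NoiseModel(c(0, 0, 0)))
  f2 <- assembleField(mesh, u * sqrt(2), mat, NoiseModel(c(0, 0, 0)))

  same <- energyChangeMap(f1, f1, gridSpacing = 10)
  expect_equal(max(abs(same$change), na.rm = TRUE), 0)
  dbl <- energyChangeMap(f1, f2, gridSpacing = 10)
  expect_equal(median(dbl$change, na.rm = TRUE), 1, tolerance = 1e-6)

  far <- mesh
  far@nodes <- far@nodes + 1e4
  f3 <- assembleField(far, u, mat, NoiseModel(c(0, 0, 0)))
  expect_error(energyChangeMap(f1, f3), "disjoint")
})
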