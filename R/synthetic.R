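# Ground-truth synthetic scenes: bead fields, analytic displacement models,
# and rendered image stacks.

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a hard-sphere bead field
#'
#' Draws bead positions uniformly in a box at a density of
#' `1 / meanSpacing^3` (the reference gels have ~24 um mean bead spacing),
#' rejecting candidates closer than `minSeparation` to an accepted bead.
#' Deterministic for a fixed seed.
#'
#' @param box numeric(3) box edge lengths, um (origin at 0).
#' @param meanSpacing target mean bead spacing, um (default 24).
#' @param minSeparation hard-sphere exclusion distance, um.
#' @param seed integer RNG seed.
#' @return n x 3 matrix of positions, um.
#' @export
sampleBeads <- function(box, meanSpacing = 24, minSeparation = 4, seed = 1) {
  stopifnot(length(box) == 3L, all(box > 0), minSeparation < meanSpacing)
  n <- max(5L, round(prod(box) / meanSpacing^3))
  .withSeed(seed, {
    pos <- matrix(NA_real_, n, 3)
    got <- 0L
    attempts <- 0L
    while (got < n) {
      if ((attempts <- attempts + 1L) > 200L * n)
        stop("bead density infeasible for this minimum separation")
      cand <- runif(3) * box
      if (got > 0L) {
        d2 <- (pos[seq_len(got), 1] - cand[1])^2 +
              (pos[seq_len(got), 2] - cand[2])^2 +
              (pos[seq_len(got), 3] - cand[3])^2
        if (min(d2) < minSeparation^2) next
      }
      got <- got + 1L
      pos[got, ] <- cand
    }
    colnames(pos) <- c("x", "y", "z")
    pos
  })
}

#' Point-force (Kelvin) displacement field
#'
#' Classical solution for a point force in an infinite isotropic linear
#' elastic medium,
#' `u_i = F_j / (16 pi G (1 - nu) r) * ((3 - 4 nu) delta_ij + r_i r_j / r^2)`,
#' decaying as 1/r.
#'
#' @param points n x 3 evaluation points, um.
#' @param force numeric(3) force vector in N.
#' @param forceOrigin numeric(3) point of application, um.
#' @param material an [ElasticMaterial-class].
#' @return n x 3 displacements, um.
#' @export
kelvinDisplacement <- function(points, force, forceOrigin,
                               material = ElasticMaterial()) {
  points <- matrix(as.numeric(points), ncol = 3)
  R <- sweep(points, 2, forceOrigin) * 1e-6        # m
  r <- sqrt(rowSums(R^2))
  if (any(r == 0)) stop("evaluation point coincides with the force origin")
  nu <- material@poissonRatio
  A <- 1 / (16 * pi * material@shearModulus * (1 - nu))
  rf <- R %*% force                                 # r . F
  u <- A * ((3 - 4 * nu) * matrix(force, nrow(points), 3, byrow = TRUE) / r +
            R * as.numeric(rf) / r^3)
  u * 1e6                                           # um
}

# displacement gradient du_i/dx_k of the Kelvin field; returns n x 9 matrix
# in column order (11, 21, 31, 12, 22, 32, 13, 23, 33), dimensionless
.kelvinGradient <- function(points, force, forceOrigin, material) {
  points <- matrix(as.numeric(points), ncol = 3)
  R <- sweep(points, 2, forceOrigin) * 1e-6
  r <- sqrt(rowSums(R^2))
  if (any(r == 0)) stop("evaluation point coincides with the force origin")
  nu <- material@poissonRatio
  A <- 1 / (16 * pi * material@shearModulus * (1 - nu))
  rf <- as.numeric(R %*% force)
  g <- matrix(0, nrow(points), 9)
  for (i in 1:3) for (k in 1:3) {
    term <- -(3 - 4 * nu) * force[i] * R[, k] / r^3 +
      (if (i == k) rf / r^3 else 0) +
      R[, i] * force[k] / r^3 -
      3 * R[, i] * rf * R[, k] / r^5
    g[, (k - 1) * 3 + i] <- A * term
  }
  g
}

#' Contractile force-dipole displacement field
#'
#' Superposition of two opposing Kelvin point forces of equal magnitude at
#' `center +/- (separation / 2) * axis`, each pulling toward the center: a
#' minimal synthetic stand-in for a contractile cell with force generation
#' concentrated at its poles.
#'
#' @param points n x 3 evaluation points, um.
#' @param magnitude force magnitude per pole, N.
#' @param axis numeric(3) dipole axis (normalized internally).
#' @param separation pole-to-pole distance, um.
#' @param center numeric(3) dipole center, um.
#' @param material an [ElasticMaterial-class].
#' @return n x 3 displacements, um.
#' @export
dipoleDisplacement <- function(points, magnitude, axis, separation, center,
                               material = ElasticMaterial()) {
  stopifnot(separation > 0)
  axis <- axis / sqrt(sum(axis^2))
  pPlus <- center + axis * separation / 2
  pMinus <- center - axis * separation / 2
  kelvinDisplacement(points, -magnitude * axis, pPlus, material) +
    kelvinDisplacement(points, +magnitude * axis, pMinus, material)
}

#' Continuum strain-energy density of a dipole field
#'
#' Evaluates the analytic strain tensor of the dipole field (sum of the two
#' Kelvin displacement gradients) and the closed-form isotropic energy
#' density `w = lambda/2 tr(eps)^2 + G sum(eps^2)` at arbitrary points.
#' Diverges at the two force points.
#'
#' @inheritParams dipoleDisplacement
#' @return numeric(n) energy density in Pa.
#' @export
dipoleEnergyDensity <- function(points, magnitude, axis, separation, center,
                                material = ElasticMaterial()) {
  axis <- axis / sqrt(sum(axis^2))
  pPlus <- center + axis * separation / 2
  pMinus <- center - axis * separation / 2
  g <- .kelvinGradient(points, -magnitude * axis, pPlus, material) +
       .kelvinGradient(points, +magnitude * axis, pMinus, material)
  lam <- lameLambda(material)
  G <- material@shearModulus
  # eps_ij = (g_ij + g_ji) / 2 with g column order (11,21,31,12,22,32,13,23,33)
  tr <- g[, 1] + g[, 5] + g[, 9]
  sumsq <- g[, 1]^2 + g[, 5]^2 + g[, 9]^2 +
    2 * (((g[, 2] + g[, 4]) / 2)^2 + ((g[, 3] + g[, 7]) / 2)^2 +
         ((g[, 6] + g[, 8]) / 2)^2)
  0.5 * lam * tr^2 + G * sumsq
}

#' Affine (uniform-strain) displacement field
#'
#' `u(x) = (R - I + eps) (x - x0) + t`: a rigid rotation plus uniform strain
#' plus translation. Constant-strain tetrahedra reproduce such fields
#' exactly, which makes this model the exactness oracle for the element
#' formulation.
#'
#' @param points n x 3 evaluation points, um.
#' @param strain 3 x 3 symmetric strain tensor (dimensionless).
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation numeric(3), um.
#' @param center numeric(3) reference point x0, um.
#' @return n x 3 displacements, um.
#' @export
affineDisplacement <- function(points, strain = diag(0, 3),
                               rotation = diag(3), translation = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  points <- matrix(as.numeric(points), ncol = 3)
  X <- sweep(points, 2, center)
  X %*% t(rotation - diag(3) + strain) +
    matrix(translation, nrow(points), 3, byrow = TRUE)
}

#' Render bead positions into an image stack
#'
#' Sums anisotropic Gaussian blobs (an idealized point-spread function)
#' sampled at voxel centers, with optional Poisson shot noise or additive
#' Gaussian read noise. The default PSF sigmas (0.4, 0.4, 1.5) um approximate
#' a 1 um bead imaged with a low-NA air objective; the default voxel pitch is
#' the reference acquisition's (0.645, 0.645, 2.0) um.
#'
#' @param positions n x 3 bead positions, um.
#' @param box numeric(3) physical stack extent, um (origin at 0).
#' @param spacing numeric(3) voxel pitch, um.
#' @param psfSigma numeric(3) Gaussian PSF sigmas, um.
#' @param intensity peak blob intensity (photons for Poisson noise).
#' @param noise "none", "gaussian" or "poisson".
#' @param noiseSd additive noise SD (gaussian only).
#' @param seed RNG seed for the noise draw.
#' @return an [ImageStack-class]
#' @export
renderStack <- function(positions, box, spacing = c(0.645, 0.645, 2.0),
                        psfSigma = c(0.4, 0.4, 1.5), intensity = 1000,
                        noise = c("none", "gaussian", "poisson"),
                        noiseSd = 10, seed = 1) {
  noise <- match.arg(noise)
  positions <- matrix(as.numeric(positions), ncol = 3)
  dims <- pmax(1L, as.integer(round(box / spacing)))
  vox <- .cpp_render(positions, rep(intensity, length.out = max(1, nrow(positions))),
                     dims, spacing, c(0, 0, 0), psfSigma)
  if (noise == "gaussian") {
    vox <- .withSeed(seed, pmax(vox + rnorm(length(vox), 0, noiseSd), 0))
  } else if (noise == "poisson") {
    vox <- .withSeed(seed, as.numeric(rpois(length(vox), vox)))
  }
  ImageStack(array(vox, dims), spacing = spacing, origin = c(0, 0, 0))
}

# 4-point degree-2 quadrature with recursive octasection; f maps an n x 3
# matrix of um points to densities in Pa; returns energy in Pa*um^3
.integrateOverTets <- function(f, nodes, elements, depth = 2) {
  verts <- lapply(1:4, function(j) nodes[elements[, j], , drop = FALSE])
  for (d in seq_len(depth)) {
    m <- list(ab = (verts[[1]] + verts[[2]]) / 2,
              ac = (verts[[1]] + verts[[3]]) / 2,
              ad = (verts[[1]] + verts[[4]]) / 2,
              bc = (verts[[2]] + verts[[3]]) / 2,
              bd = (verts[[2]] + verts[[4]]) / 2,
              cd = (verts[[3]] + verts[[4]]) / 2)
    sub <- list(
      list(verts[[1]], m$ab, m$ac, m$ad),
      list(verts[[2]], m$ab, m$bc, m$bd),
      list(verts[[3]], m$ac, m$bc, m$cd),
      list(verts[[4]], m$ad, m$bd, m$cd),
      list(m$ab, m$cd, m$ac, m$ad),
      list(m$ab, m$cd, m$ad, m$bd),
      list(m$ab, m$cd, m$bd, m$bc),
      list(m$ab, m$cd, m$bc, m$ac))
    verts <- lapply(1:4, function(j) do.call(rbind, lapply(sub, `[[`, j)))
  }
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  W <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  u <- verts[[2]] - verts[[1]]
  v <- verts[[3]] - verts[[1]]
  w <- verts[[4]] - verts[[1]]
  vol <- abs(u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
             u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
             u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  total <- 0
  for (p in 1:4) {
    pts <- W[p, 1] * verts[[1]] + W[p, 2] * verts[[2]] +
           W[p, 3] * verts[[3]] + W[p, 4] * verts[[4]]
    total <- total + sum(f(pts) * vol) / 4
  }
  total
}

#' Integrate the analytic dipole energy density
#'
#' Continuum strain energy of a dipole ground-truth field, either over a
#' spherical shell (Gauss-Legendre in radius and polar angle, trapezoid in
#' azimuth) or over a set of tetrahedra (degree-2 quadrature after recursive
#' subdivision). The shell form defines the manifest energy of a dipole
#' scene; the tetrahedron form evaluates the same integrand over exactly the
#' volume covered by a mesh's elements, for discretization-error studies.
#'
#' @param magnitude,axis,separation,center,material dipole parameters, as in
#'   [dipoleDisplacement()].
#' @param shell numeric(2) inner/outer shell radii around `center`, um (must
#'   exclude the force points).
#' @param mesh optional [TetMesh-class]; with `elementSubset`, integrates
#'   over those elements instead of the shell.
#' @param elementSubset integer indices of elements to integrate over.
#' @param nr,ntheta,nphi shell quadrature orders.
#' @param depth tetrahedron subdivision depth.
#' @return energy in pJ.
#' @export
dipoleFieldEnergy <- function(magnitude, axis, separation, center,
                              material = ElasticMaterial(), shell = NULL,
                              mesh = NULL, elementSubset = NULL,
                              nr = 48, ntheta = 32, nphi = 64, depth = 2) {
  densf <- function(pts) dipoleEnergyDensity(pts, magnitude, axis, separation,
                                             center, material)
  if (!is.null(mesh)) {
    el <- mesh@elements
    if (!is.null(elementSubset)) el <- el[elementSubset, , drop = FALSE]
    return(.integrateOverTets(densf, mesh@nodes, el, depth) * .PJ_PER_PA_UM3)
  }
  stopifnot(length(shell) == 2L, shell[1] < shell[2],
            shell[1] > separation / 2)
  gr <- pracma::gaussLegendre(nr, shell[1], shell[2])
  gt <- pracma::gaussLegendre(ntheta, -1, 1)        # cos(theta)
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  total <- 0
  for (it in seq_len(ntheta)) {
    ct <- gt$x[it]
    st <- sqrt(1 - ct^2)
    for (ip in seq_len(nphi)) {
      dirv <- c(st * cos(phi[ip]), st * sin(phi[ip]), ct)
      pts <- outer(gr$x, dirv) + matrix(center, nr, 3, byrow = TRUE)
      total <- total + sum(gr$w * gr$x^2 * densf(pts)) * gt$w[it] *
        (2 * pi / nphi)
    }
  }
  total * .PJ_PER_PA_UM3
}

# distance of points to the segment [a, b]
.distToSegment <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- pmin(pmax((sweep(p, 2, a) %*% ab) / L2, 0), 1)
  proj <- matrix(a, nrow(p), 3, byrow = TRUE) + outer(as.numeric(t), ab)
  sqrt(rowSums((p - proj)^2))
}

#' Generate a contractile-dipole ground-truth scene
#'
#' Samples a bead field at the reference density (~24 um mean spacing) and
#' displaces it with the analytic contractile-dipole field. The dipole
#' emulates an elongated spindle-shaped cell: the cell body is a bead-free
#' capsule of radius `cellRadius` around the dipole axis (beads sit only in
#' the gel, and the point-force field is singular at the poles inside the
#' cell). Defaults describe a ~80 x 30 um spindle cell whose 15 nN pole
#' forces produce a peak gel strain of about 5%, the upper end of the gel's
#' linear regime.
#'
#' The manifest records the exact per-bead displacements and two analytic
#' continuum energies of the ground-truth field: `analytic_shell_energy_pJ`
#' over a spherical shell clear of the cell, and `analytic_gel_energy_pJ`
#' over the whole gel domain within the integration radius (ball of radius
#' `outer_radius_um` minus the cell capsule). Rendering the paired
#' relaxed/deformed stacks is done lazily by [sceneStacks()].
#'
#' @param box numeric(3) box edge lengths, um.
#' @param meanSpacing mean bead spacing, um (default 24).
#' @param magnitude force per pole, N (default 1.5e-8, i.e. 15 nN).
#' @param separation pole separation, um (default 50).
#' @param cellRadius radius of the bead-free cell capsule, um (default 15).
#' @param axis dipole axis.
#' @param material an [ElasticMaterial-class].
#' @param spacing,psfSigma,intensity,noise rendering parameters (see
#'   [renderStack()]).
#' @param seed integer seed; regenerating with the same seed reproduces the
#'   scene exactly.
#' @param computeAnalytic set FALSE to skip the quadratures (faster when the
#'   scene is only used for rendering or anisotropy work).
#' @return a [SyntheticScene-class]
#' @export
dipoleScene <- function(box = c(240, 240, 240), meanSpacing = 24,
                        magnitude = 1.5e-8, separation = 50, cellRadius = 15,
                        axis = c(1, 0, 0), material = ElasticMaterial(),
                        spacing = c(0.645, 0.645, 2.0),
                        psfSigma = c(0.4, 0.4, 1.5), intensity = 1000,
                        noise = "none", seed = 1, computeAnalytic = TRUE) {
  center <- box / 2
  axis <- axis / sqrt(sum(axis^2))
  pPlus <- center + axis * separation / 2
  pMinus <- center - axis * separation / 2
  pos <- sampleBeads(box, meanSpacing = meanSpacing, seed = seed)
  pos <- pos[.distToSegment(pos, pMinus, pPlus) > cellRadius, , drop = FALSE]
  u <- dipoleDisplacement(pos, magnitude, axis, separation, center, material)
  rCell <- separation / 2 + cellRadius      # sphere enclosing the capsule
  rOut <- min(box) / 2 - meanSpacing
  shell <- c(rCell, rOut)
  manifest <- list(displacements = u, center = center,
                   cell_radius_um = cellRadius, shell_um = shell,
                   outer_radius_um = rOut)
  if (computeAnalytic) {
    manifest$analytic_shell_energy_pJ <-
      dipoleFieldEnergy(magnitude, axis, separation, center, material,
                        shell = shell)
    # gel energy inside the enclosing sphere: midpoint grid on ball \ capsule
    h <- 0.5
    g <- seq(-rCell + h / 2, rCell - h / 2, by = h)
    pts <- as.matrix(expand.grid(g, g, g))
    pts <- pts[rowSums(pts^2) < rCell^2, , drop = FALSE]
    pts <- sweep(pts, 2, center, "+")
    keep <- .distToSegment(pts, pMinus, pPlus) > cellRadius
    inner <- sum(dipoleEnergyDensity(pts[keep, , drop = FALSE], magnitude,
                                     axis, separation, center, material)) *
      h^3 * .PJ_PER_PA_UM3
    manifest$analytic_gel_energy_pJ <-
      manifest$analytic_shell_energy_pJ + inner
  }
  new("SyntheticScene", box = as.numeric(box), positions = pos,
      model = "dipole",
      params = list(magnitude_N = magnitude, separation_um = separation,
                    cell_radius_um = cellRadius, axis = axis, center = center,
                    mean_spacing_um = meanSpacing),
      material = material, spacing = as.numeric(spacing),
      psfSigma = as.numeric(psfSigma), intensity = intensity, noise = noise,
      seed = as.integer(seed), manifest = manifest)
}

#' Render the relaxed/deformed stack pair of a scene
#'
#' The relaxed stack images the beads at their reference positions; the
#' deformed stack images them displaced by the scene's ground-truth field.
#'
#' @param scene a [SyntheticScene-class].
#' @return list with `relaxed` and `deformed` [ImageStack-class] objects.
#' @export
sceneStacks <- function(scene) {
  u <- scene@manifest$displacements
  list(
    relaxed = renderStack(scene@positions, scene@box, scene@spacing,
                          scene@psfSigma, scene@intensity, scene@noise,
                          seed = scene@seed),
    deformed = renderStack(scene@positions + u, scene@box, scene@spacing,
                           scene@psfSigma, scene@intensity, scene@noise,
                           seed = scene@seed + 1L))
}
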