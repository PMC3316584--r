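# Linear tetrahedral finite-element strain energy with noise-baseline
# subtraction.
#
# Internally energies are Pa*um^3; reported energies are pJ (1 Pa*um^3 =
# 1e-6 pJ), so U[pJ] = w[Pa] * V[um^3] * 1e-6 holds exactly.

.PJ_PER_PA_UM3 <- 1e-6

# isotropic stiffness in Voigt notation (engineering shear strains)
.isotropicC <- function(material) {
  G <- material@shearModulus
  lam <- lameLambda(material)
  C <- diag(c(rep(2 * G, 3), rep(G, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C
}

# shape-function gradients of the constant-strain tetrahedron: row i is
# grad N_i; N_i is the linear interpolant with N_i(x_j) = delta_ij
.shapeGradients <- function(elementNodes) {
  A <- cbind(1, elementNodes)
  B <- solve(t(A))          # N(x) = B %*% c(1, x)
  B[, 2:4, drop = FALSE]
}

#' Stiffness matrix of a linear (constant-strain) tetrahedron
#'
#' Builds `K = V * t(B) %*% C %*% B` for the 4-node tetrahedron with linear
#' shape functions, where C is the isotropic elasticity matrix from the gel's
#' shear modulus and Poisson ratio. Displacements inside the element are
#' linear interpolations of the nodal values, so strain and stress are
#' uniform per element and the element is exact for affine displacement
#' fields. K is symmetric positive semi-definite with a 6-dimensional null
#' space (3 translations, 3 linearized rotations). Units: with nodes in um
#' and displacements in um, `0.5 * u %*% K %*% u` is energy in Pa*um^3
#' (1e-6 pJ). DOF ordering is (x1, y1, z1, x2, ..., z4).
#'
#' @param elementNodes 4 x 3 vertex coordinates, um.
#' @param material an [ElasticMaterial-class].
#' @return 12 x 12 stiffness matrix.
#' @examples
#' K <- elementStiffness(rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)),
#'                       ElasticMaterial(118, 0.35))
#' range(K - t(K))  # symmetric
#' @export
elementStiffness <- function(elementNodes, material = ElasticMaterial()) {
  elementNodes <- as.matrix(elementNodes)
  stopifnot(nrow(elementNodes) == 4L, ncol(elementNodes) == 3L)
  V <- .tetVolumes(elementNodes, matrix(1:4, nrow = 1))
  if (V <= 0) stop("zero-volume element")
  grads <- .shapeGradients(elementNodes)
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    cx <- 3 * i - 2
    g <- grads[i, ]
    B[1, cx]     <- g[1]
    B[2, cx + 1] <- g[2]
    B[3, cx + 2] <- g[3]
    B[4, cx]     <- g[2]; B[4, cx + 1] <- g[1]
    B[5, cx + 1] <- g[3]; B[5, cx + 2] <- g[2]
    B[6, cx]     <- g[3]; B[6, cx + 2] <- g[1]
  }
  K <- V * crossprod(B, .isotropicC(material) %*% B)
  (K + t(K)) / 2
}

#' Strain energy of one element
#'
#' The elastic strain energy `U = 0.5 * u' K u` stored in a deformed element,
#' in pJ. Zero for rigid translations (and, to linear order, rotations).
#'
#' @param K 12 x 12 stiffness from [elementStiffness()].
#' @param u numeric(12) nodal displacements in um, DOF order
#'   (x1, y1, z1, ..., z4); a 4 x 3 matrix is also accepted.
#' @return energy in pJ (>= 0).
#' @export
elementEnergy <- function(K, u) {
  if (is.matrix(u) && all(dim(u) == c(4L, 3L))) u <- as.numeric(t(u))
  stopifnot(length(u) == 12L, all(dim(K) == c(12L, 12L)))
  max(0.5 * sum(u * (K %*% u)), 0) * .PJ_PER_PA_UM3
}

#' Expected spurious strain energy from displacement noise
#'
#' Strain energy is quadratic in the displacements, so zero-mean measurement
#' noise contributes a positive bias. For independent zero-mean noise with
#' per-axis standard deviations sigma on every node, the expectation of
#' `0.5 * n' K n` is `0.5 * sum_i K_ii * sigma_i^2` (sigma_i being the axis
#' of DOF i). This per-element baseline is subtracted from the raw energy.
#'
#' @param K 12 x 12 element stiffness.
#' @param noise a [NoiseModel-class].
#' @return expected spurious energy in pJ.
#' @export
noiseBaseline <- function(K, noise = NoiseModel()) {
  sig <- rep(noise@sigma, 4L)
  0.5 * sum(diag(K) * sig^2) * .PJ_PER_PA_UM3
}

#' Continuum strain-energy density of a uniform strain
#'
#' Closed form `w = lambda/2 * tr(eps)^2 + G * sum(eps_ij^2)` for a small
#' (symmetrized) strain tensor, in Pa.
#'
#' @param strain 3 x 3 strain tensor (symmetrized internally).
#' @param material an [ElasticMaterial-class].
#' @return energy density in Pa.
#' @export
continuumEnergyDensity <- function(strain, material = ElasticMaterial()) {
  eps <- (strain + t(strain)) / 2
  0.5 * lameLambda(material) * sum(diag(eps))^2 +
    material@shearModulus * sum(eps^2)
}

# per-element displacement 12-vectors as an m x 12 matrix
.elementDisplacements <- function(mesh, disp) {
  el <- mesh@elements
  cbind(disp[el[, 1], , drop = FALSE], disp[el[, 2], , drop = FALSE],
        disp[el[, 3], , drop = FALSE], disp[el[, 4], , drop = FALSE])
}

#' Assemble the strain energy density field
#'
#' Computes per-element raw strain energy from the nodal (bead) displacements,
#' subtracts the expected noise baseline, converts to energy density, and
#' fills the densities of quality-excluded elements from the nearest valid
#' element centroid. Corrected energies may be negative after baseline
#' subtraction and are deliberately retained unfloored so that integrated
#' totals remain unbiased.
#'
#' @param mesh a [TetMesh-class] over the relaxed bead positions.
#' @param disp nodal displacements: an n x 3 matrix aligned with
#'   `nodes(mesh)`, or a [MatchedDisplacements-class] whose non-lost beads
#'   are the mesh nodes.
#' @param material an [ElasticMaterial-class].
#' @param noise a [NoiseModel-class]; use `NoiseModel(c(0, 0, 0))` for
#'   noise-free synthetic input.
#' @return a [StrainEnergyField-class]
#' @export
assembleField <- function(mesh, disp, material = ElasticMaterial(),
                          noise = NoiseModel()) {
  stopifnot(is(mesh, "TetMesh"))
  if (is(disp, "MatchedDisplacements"))
    disp <- displacements(disp)[!lostMask(disp), , drop = FALSE]
  disp <- as.matrix(disp)
  if (nrow(disp) != nrow(mesh@nodes))
    stop("displacements must correspond 1:1 to mesh nodes")
  if (!any(mesh@validMask)) stop("no valid elements remain")

  m <- nrow(mesh@elements)
  U <- numeric(m)
  base <- numeric(m)
  uel <- .elementDisplacements(mesh, disp)
  sig2 <- rep(noise@sigma, 4L)^2
  for (e in seq_len(m)) {
    K <- elementStiffness(mesh@nodes[mesh@elements[e, ], ], material)
    U[e] <- max(0.5 * sum(uel[e, ] * (K %*% uel[e, ])), 0) * .PJ_PER_PA_UM3
    base[e] <- 0.5 * sum(diag(K) * sig2) * .PJ_PER_PA_UM3
  }
  corrected <- U - base
  density <- corrected / mesh@volumes / .PJ_PER_PA_UM3   # Pa

  valid <- mesh@validMask
  filled <- !valid
  fillSource <- rep(NA_integer_, m)
  if (any(filled)) {
    cen <- elementCentroids(mesh)
    vidx <- which(valid)
    vcen <- cen[vidx, , drop = FALSE]
    for (e in which(filled)) {
      d2 <- (vcen[, 1] - cen[e, 1])^2 + (vcen[, 2] - cen[e, 2])^2 +
            (vcen[, 3] - cen[e, 3])^2
      src <- vidx[which.min(d2)]
      fillSource[e] <- src
      density[e] <- density[src]
      corrected[e] <- density[src] * mesh@volumes[e] * .PJ_PER_PA_UM3
    }
  }
  new("StrainEnergyField", mesh = mesh, rawEnergy = U, baseline = base,
      correctedEnergy = corrected, density = density, filled = filled,
      fillSource = fillSource)
}

#' Total strain energy around a center
#'
#' Integrates the corrected strain energy over increasingly large spheres
#' around the cell: the cumulative sum of corrected element energies (valid
#' plus nearest-neighbor-filled) whose centroids lie within each radius. The
#' curve is not forced to be monotone -- corrected energies can be negative
#' -- and its value at the largest radius is the plateau, the scalar total
#' strain energy of the cell.
#'
#' @param field a [StrainEnergyField-class].
#' @param center numeric(3) integration center, um (typically the cell
#'   centroid).
#' @param radii increasing radii in um; `Inf` sums every element.
#' @return list with `radii_um`, `cumulative_pJ`, and `plateau_pJ`.
#' @export
totalEnergy <- function(field, center,
                        radii = seq(20, 150, by = 10)) {
  stopifnot(is(field, "StrainEnergyField"), length(center) == 3L)
  radii <- sort(radii)
  cen <- elementCentroids(field@mesh)
  r <- sqrt((cen[, 1] - center[1])^2 + (cen[, 2] - center[2])^2 +
            (cen[, 3] - center[3])^2)
  cum <- vapply(radii, function(R) sum(field@correctedEnergy[r <= R]),
                numeric(1))
  list(radii_um = radii, cumulative_pJ = cum,
       plateau_pJ = cum[length(cum)])
}

#' Relative change in strain energy density between two time points
#'
#' Rasterizes both density fields (floored at 0) onto a common regular grid
#' by point-in-tetrahedron lookup and returns the signed relative change
#' `(w2 - w1) / max(w1, floor)` per grid point: negative where tension is
#' released, positive where it builds up. The floor avoids division blow-up
#' in low-energy regions and defaults to 1% of the first frame's maximum
#' density.
#'
#' @param field1,field2 [StrainEnergyField-class] objects over the same gel.
#' @param gridSpacing grid pitch in um (default 5).
#' @param floorFrac floor as a fraction of `max(density(field1))`.
#' @return list with grid axis vectors `x_um`, `y_um`, `z_um`, the 3D array
#'   `change`, and the `floor_Pa` used. Grid points outside either mesh are NA.
#' @export
energyChangeMap <- function(field1, field2, gridSpacing = 5,
                            floorFrac = 0.01) {
  b1 <- apply(field1@mesh@nodes, 2, range)
  b2 <- apply(field2@mesh@nodes, 2, range)
  lo <- pmax(b1[1, ], b2[1, ])
  hi <- pmin(b1[2, ], b2[2, ])
  if (any(lo >= hi)) stop("mesh bounding boxes are disjoint")
  ax <- lapply(1:3, function(k) seq(lo[k] + gridSpacing / 2, hi[k],
                                    by = gridSpacing))
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  w1 <- pmax(field1@density, 0)
  w2 <- pmax(field2@density, 0)
  cell <- 2 * gridSpacing + mean(c(b1[2, ] - b1[1, ])) / 10
  i1 <- .cpp_point_in_tets(grid, field1@mesh@nodes, field1@mesh@elements, cell)
  i2 <- .cpp_point_in_tets(grid, field2@mesh@nodes, field2@mesh@elements, cell)
  floorPa <- floorFrac * max(w1)
  chg <- rep(NA_real_, nrow(grid))
  ok <- !is.na(i1) & !is.na(i2)
  chg[ok] <- (w2[i2[ok]] - w1[i1[ok]]) / pmax(w1[i1[ok]], floorPa)
  list(x_um = ax[[1]], y_um = ax[[2]], z_um = ax[[3]],
       change = array(chg, lengths(ax)), floor_Pa = floorPa)
}
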