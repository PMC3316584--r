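#' @import methods
#' @importFrom stats rnorm rpois runif sd quantile setNames
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib tfm3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ImageStack: a 3D fluorescence image with physical voxel spacing
#'
#' Container for one confocal/widefield z-stack. Voxel `[i, j, k]` (1-based)
#' has its center at `origin + (c(i, j, k) - 0.5) * spacing`; all positions in
#' the package are physical micrometer coordinates, never voxel indices.
#'
#' @slot voxels 3D numeric array of non-negative intensities, indexed
#'   `[x, y, z]`.
#' @slot spacing numeric(3), voxel pitch (dx, dy, dz) in um; dz is the
#'   z-section interval (2 um in the reference acquisition).
#' @slot origin numeric(3), physical coordinate of the stack corner in um.
#' @export
setClass("ImageStack",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- NULL
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (um)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (um)")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msg <- c(msg, "intensities must be finite")
  if (is.null(msg)) TRUE else msg
})

#' BeadSet: detected marker-bead centers
#'
#' @slot positions n x 3 matrix of bead centers in um.
#' @slot sourceStack character identifier of the stack the beads came from.
#' @export
setClass("BeadSet",
  representation(positions = "matrix", sourceStack = "character"))

setValidity("BeadSet", function(object) {
  if (ncol(object@positions) != 3L) return("positions must be n x 3 (um)")
  if (nrow(object@positions) > 0 && any(!is.finite(object@positions)))
    return("positions must be finite")
  TRUE
})

#' MatchedDisplacements: per-bead displacement measurements
#'
#' Reference (relaxed-state) bead positions together with the displacement
#' vectors deformed-minus-relaxed, the sum-of-squared-differences residual of
#' each subvolume match, and a flag for beads that could not be matched.
#'
#' @slot refPositions n x 3 matrix, um.
#' @slot displacements n x 3 matrix, um (NA where lost).
#' @slot residuals numeric(n), SSD at the match optimum (>= 0).
#' @slot lost logical(n).
#' @slot provenance list of tracking parameters (subvolume, search radius,
#'   drift correction applied).
#' @export
setClass("MatchedDisplacements",
  representation(refPositions = "matrix", displacements = "matrix",
                 residuals = "numeric", lost = "logical",
                 provenance = "list"))

setValidity("MatchedDisplacements", function(object) {
  n <- nrow(object@refPositions)
  msg <- NULL
  if (ncol(object@refPositions) != 3L || ncol(object@displacements) != 3L)
    msg <- c(msg, "position and displacement matrices must be n x 3")
  if (nrow(object@displacements) != n || length(object@residuals) != n ||
      length(object@lost) != n)
    msg <- c(msg, "slots must have congruent lengths")
  if (any(object@residuals < 0, na.rm = TRUE))
    msg <- c(msg, "residuals must be >= 0")
  if (n > 0 && any(!is.finite(object@displacements[!object@lost, ])))
    msg <- c(msg, "displacements must be finite where not lost")
  if (is.null(msg)) TRUE else msg
})

#' ElasticMaterial: isotropic linear elastic gel parameters
#'
#' @slot shearModulus shear modulus G in Pa (default 118 Pa for the reference
#'   collagen gel).
#' @slot poissonRatio Poisson's ratio (default 0.35).
#' @export
setClass("ElasticMaterial",
  representation(shearModulus = "numeric", poissonRatio = "numeric"))

setValidity("ElasticMaterial", function(object) {
  if (length(object@shearModulus) != 1L || object@shearModulus <= 0)
    return("shear modulus must be a single positive value (Pa)")
  if (length(object@poissonRatio) != 1L || object@poissonRatio <= -1 ||
      object@poissonRatio >= 0.5)
    return("Poisson ratio must lie in (-1, 0.5)")
  TRUE
})

#' NoiseModel: per-axis bead displacement measurement error
#'
#' Standard deviations of the zero-mean displacement measurement noise, used
#' for the expected spurious-strain-energy baseline. Defaults correspond to
#' the tracker's accuracy: 22 nm laterally, 130 nm axially.
#'
#' @slot sigma numeric(3), (sigma_x, sigma_y, sigma_z) in um.
#' @export
setClass("NoiseModel", representation(sigma = "numeric"))

setValidity("NoiseModel", function(object) {
  if (length(object@sigma) != 3L || any(!is.finite(object@sigma)) ||
      any(object@sigma < 0))
    return("sigma must be 3 non-negative finite values (um)")
  TRUE
})

#' TetMesh: Delaunay tetrahedral finite-element mesh over bead positions
#'
#' @slot nodes n x 3 matrix of node coordinates in um (relaxed bead positions).
#' @slot elements m x 4 integer matrix of node indices (1-based).
#' @slot volumes numeric(m), element volumes in um^3.
#' @slot quality numeric(m), shape factor q between 0 and 1 (1 = regular
#'   tetrahedron, 0 = degenerate/flat).
#' @slot validMask logical(m), FALSE for elements excluded by the quality
#'   filter.
#' @export
setClass("TetMesh",
  representation(nodes = "matrix", elements = "matrix", volumes = "numeric",
                 quality = "numeric", validMask = "logical"))

setValidity("TetMesh", function(object) {
  msg <- NULL
  m <- nrow(object@elements)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
  if (ncol(object@elements) != 4L) msg <- c(msg, "elements must be m x 4")
  if (m > 0 && any(apply(object@elements, 1L, anyDuplicated) > 0))
    msg <- c(msg, "each element must reference 4 distinct nodes")
  if (length(object@volumes) != m || length(object@quality) != m ||
      length(object@validMask) != m)
    msg <- c(msg, "per-element slots must have length m")
  if (any(object@volumes < 0)) msg <- c(msg, "volumes must be >= 0")
  if (any(object@quality < -1e-12 | object@quality > 1 + 1e-12))
    msg <- c(msg, "quality must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' StrainEnergyField: per-element strain energy and density
#'
#' Raw per-element strain energies, the expected spurious energy from
#' displacement noise (baseline), the baseline-corrected energies, and the
#' energy density. Densities of quality-excluded elements are filled from the
#' nearest valid element; `fillSource` records where each filled value came
#' from. Units: energy in pJ, density in Pa; the unit relation
#' `U[pJ] = w[Pa] * V[um^3] * 1e-6` holds exactly for computed elements.
#'
#' @slot mesh a [TetMesh-class].
#' @slot rawEnergy numeric(m), uncorrected energy in pJ (>= 0).
#' @slot baseline numeric(m), expected noise energy in pJ.
#' @slot correctedEnergy numeric(m), rawEnergy - baseline, pJ (may be
#'   negative; retained unfloored so totals stay unbiased).
#' @slot density numeric(m), corrected energy density in Pa (filled on
#'   invalid elements).
#' @slot filled logical(m), TRUE where density was nearest-neighbor filled.
#' @slot fillSource integer(m), index of the valid element that supplied a
#'   filled density (NA for computed elements).
#' @export
setClass("StrainEnergyField",
  representation(mesh = "TetMesh", rawEnergy = "numeric", baseline = "numeric",
                 correctedEnergy = "numeric", density = "numeric",
                 filled = "logical", fillSource = "integer"))

setValidity("StrainEnergyField", function(object) {
  m <- nrow(object@mesh@elements)
  msg <- NULL
  if (length(object@rawEnergy) != m || length(object@baseline) != m ||
      length(object@correctedEnergy) != m || length(object@density) != m ||
      length(object@filled) != m || length(object@fillSource) != m)
    msg <- c(msg, "per-element slots must have length m")
  if (any(object@rawEnergy < -1e-12, na.rm = TRUE))
    msg <- c(msg, "raw energies must be >= 0")
  if (any(!is.finite(object@density)))
    msg <- c(msg, "density must be finite everywhere (filled where invalid)")
  if (is.null(msg)) TRUE else msg
})

#' AnisotropyResult: second-moment anisotropy of a shape or field
#'
#' @slot tensor centered second-moment matrix (2x2 for contours, 3x3 for
#'   energy fields), um^2 times weight units.
#' @slot eigenvalues sorted descending.
#' @slot index lambda_max / lambda_min, >= 1 (1 = isotropic).
#' @slot centroid weight-centroid the moments were centered at, um.
#' @export
setClass("AnisotropyResult",
  representation(tensor = "matrix", eigenvalues = "numeric",
                 index = "numeric", centroid = "numeric"))

setValidity("AnisotropyResult", function(object) {
  if (length(object@index) != 1L || object@index < 1 - 1e-9)
    return("anisotropy index must be a single value >= 1")
  if (max(abs(object@tensor - t(object@tensor))) > 1e-8 * max(1, abs(object@tensor)))
    return("second-moment tensor must be symmetric")
  TRUE
})

#' InvasionProfile: cumulative invasion-depth distribution
#'
#' The profile at depth d is the fraction of cells lying at or below depth d
#' under the gel surface: a right-continuous, non-increasing step function
#' with value 1 at depth 0.
#'
#' @slot depths sorted per-cell invasion depths in um (>= 0).
#' @slot surfaceZ estimated (or supplied) gel surface z in um.
#' @slot nCells number of cells.
#' @export
setClass("InvasionProfile",
  representation(depths = "numeric", surfaceZ = "numeric", nCells = "integer"))

setValidity("InvasionProfile", function(object) {
  if (object@nCells < 1L) return("profile needs at least one cell")
  if (any(object@depths < 0)) return("depths must be >= 0")
  if (is.unsorted(object@depths)) return("depths must be sorted")
  TRUE
})

#' SyntheticScene: ground-truth scene for validation
#'
#' A bead field in a box, an analytic elastic displacement model, rendering
#' parameters, and a manifest holding the exact per-bead displacements plus
#' (for dipole scenes) the analytic continuum energy in a stated shell.
#'
#' @slot box numeric(3), box edge lengths in um (origin at 0).
#' @slot positions n x 3 bead positions, um.
#' @slot model one of "dipole", "kelvin", "affine", "none".
#' @slot params list of model parameters.
#' @slot material an [ElasticMaterial-class].
#' @slot spacing,psfSigma numeric(3) rendering voxel pitch and Gaussian PSF
#'   sigmas, um.
#' @slot intensity peak bead intensity (arbitrary units).
#' @slot noise one of "none", "gaussian", "poisson".
#' @slot seed integer RNG seed; the same seed regenerates the scene exactly.
#' @slot manifest list: `displacements` (n x 3, um), plus model-specific
#'   ground truth (e.g. `shell`, `analytic_energy_pJ`).
#' @export
setClass("SyntheticScene",
  representation(box = "numeric", positions = "matrix", model = "character",
                 params = "list", material = "ElasticMaterial",
                 spacing = "numeric", psfSigma = "numeric",
                 intensity = "numeric", noise = "character", seed = "integer",
                 manifest = "list"))
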