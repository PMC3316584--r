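# Constructors, accessors and show() methods.

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array, indexed `[x, y, z]`.
#' @param spacing numeric(3) voxel pitch in um.
#' @param origin numeric(3) corner coordinate in um.
#' @return an [ImageStack-class]
#' @examples
#' st <- ImageStack(array(0, c(8, 8, 4)), spacing = c(0.645, 0.645, 2))
#' spacing(st)
#' @export
ImageStack <- function(voxels, spacing = c(0.645, 0.645, 2.0),
                       origin = c(0, 0, 0)) {
  new("ImageStack", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BeadSet
#' @param positions n x 3 matrix of um coordinates.
#' @param sourceStack identifier of the originating stack.
#' @return a [BeadSet-class]
#' @export
BeadSet <- function(positions, sourceStack = "") {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  new("BeadSet", positions = positions, sourceStack = sourceStack)
}

#' Construct an ElasticMaterial
#' @param shearModulus G in Pa.
#' @param poissonRatio dimensionless, in (-1, 0.5).
#' @return an [ElasticMaterial-class]
#' @examples
#' collagen <- ElasticMaterial(118, 0.35)
#' lameLambda(collagen)
#' @export
ElasticMaterial <- function(shearModulus = 118, poissonRatio = 0.35) {
  new("ElasticMaterial", shearModulus = as.numeric(shearModulus),
      poissonRatio = as.numeric(poissonRatio))
}

#' Construct a NoiseModel
#' @param sigma numeric(3) displacement-noise SDs in um; the default is the
#'   tracker accuracy (22 nm lateral, 130 nm axial).
#' @return a [NoiseModel-class]
#' @export
NoiseModel <- function(sigma = c(0.022, 0.022, 0.130)) {
  new("NoiseModel", sigma = as.numeric(sigma))
}

#' @rdname ImageStack-class
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)

#' @rdname ImageStack-class
#' @export
setMethod("spacing", "ImageStack", function(object) object@spacing)

#' @rdname ImageStack-class
#' @export
setMethod("origin", "ImageStack", function(object) object@origin)

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@voxels))

#' Physical bounds of a stack
#'
#' @param object an [ImageStack-class]
#' @return 2 x 3 matrix (rows: lower, upper) of the physical extent in um.
#' @export
stackBounds <- function(object) {
  rbind(lower = object@origin,
        upper = object@origin + dim(object@voxels) * object@spacing)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f um, intensity range [%.3g, %.3g]\n",
              d[1] * object@spacing[1], d[2] * object@spacing[2],
              d[3] * object@spacing[3], min(object@voxels),
              max(object@voxels)))
})

#' @rdname BeadSet-class
#' @export
setMethod("positions", "BeadSet", function(object) object@positions)

#' @rdname BeadSet-class
#' @export
setMethod("length", "BeadSet", function(x) nrow(x@positions))

setMethod("show", "BeadSet", function(object) {
  cat(sprintf("BeadSet: %d beads", nrow(object@positions)))
  if (nzchar(object@sourceStack))
    cat(sprintf(" from '%s'", object@sourceStack))
  cat("\n")
})

#' @rdname MatchedDisplacements-class
#' @export
setMethod("positions", "MatchedDisplacements", function(object)
  object@refPositions)

#' @rdname MatchedDisplacements-class
#' @export
setMethod("displacements", "MatchedDisplacements", function(object)
  object@displacements)

#' @rdname MatchedDisplacements-class
#' @export
setMethod("matchResiduals", "MatchedDisplacements", function(object)
  object@residuals)

#' @rdname MatchedDisplacements-class
#' @export
setMethod("lostMask", "MatchedDisplacements", function(object) object@lost)

#' @rdname MatchedDisplacements-class
#' @export
setMethod("length", "MatchedDisplacements", function(x)
  nrow(x@refPositions))

setMethod("show", "MatchedDisplacements", function(object) {
  ok <- !object@lost
  cat(sprintf("MatchedDisplacements: %d beads (%d lost)\n",
              length(object@lost), sum(object@lost)))
  if (any(ok)) {
    mag <- sqrt(rowSums(object@displacements[ok, , drop = FALSE]^2))
    cat(sprintf("  |u|: median %.3f um, max %.3f um\n", median(mag), max(mag)))
  }
})

#' @rdname ElasticMaterial-class
#' @export
setMethod("shearModulus", "ElasticMaterial", function(object)
  object@shearModulus)

#' @rdname ElasticMaterial-class
#' @export
setMethod("poissonRatio", "ElasticMaterial", function(object)
  object@poissonRatio)

#' @rdname ElasticMaterial-class
#' @export
setMethod("lameLambda", "ElasticMaterial", function(object)
  2 * object@shearModulus * object@poissonRatio / (1 - 2 * object@poissonRatio))

setMethod("show", "ElasticMaterial", function(object) {
  cat(sprintf("ElasticMaterial: G = %g Pa, nu = %g (lambda = %.4g Pa)\n",
              object@shearModulus, object@poissonRatio, lameLambda(object)))
})

#' @rdname TetMesh-class
#' @export
setMethod("nodes", "TetMesh", function(object) object@nodes)

#' @rdname TetMesh-class
#' @export
setMethod("elements", "TetMesh", function(object) object@elements)

#' @rdname TetMesh-class
#' @export
setMethod("volumes", "TetMesh", function(object) object@volumes)

#' @rdname TetMesh-class
#' @export
setMethod("quality", "TetMesh", function(object) object@quality)

#' @rdname TetMesh-class
#' @export
setMethod("validMask", "TetMesh", function(object) object@validMask)

setMethod("show", "TetMesh", function(object) {
  m <- nrow(object@elements)
  cat(sprintf("TetMesh: %d nodes, %d elements (%d valid after quality filter)\n",
              nrow(object@nodes), m, sum(object@validMask)))
  if (m > 0)
    cat(sprintf("  total volume %.4g um^3, median q %.2f\n",
                sum(object@volumes), median(object@quality)))
})

#' @rdname StrainEnergyField-class
#' @export
setMethod("rawEnergy", "StrainEnergyField", function(object) object@rawEnergy)

#' @rdname StrainEnergyField-class
#' @export
setMethod("correctedEnergy", "StrainEnergyField", function(object)
  object@correctedEnergy)

#' @rdname StrainEnergyField-class
#' @export
setMethod("energyDensity", "StrainEnergyField", function(object)
  object@density)

#' @rdname StrainEnergyField-class
#' @export
setMethod("noiseBaselines", "StrainEnergyField", function(object)
  object@baseline)

setMethod("show", "StrainEnergyField", function(object) {
  v <- object@mesh@validMask
  cat(sprintf("StrainEnergyField: %d elements (%d computed, %d filled)\n",
              length(object@density), sum(v), sum(object@filled)))
  cat(sprintf("  total corrected energy %.4g pJ, peak density %.4g Pa\n",
              sum(object@correctedEnergy[v]), max(object@density)))
})

#' @rdname AnisotropyResult-class
#' @export
setMethod("anisotropyIndex", "AnisotropyResult", function(object)
  object@index)

setMethod("show", "AnisotropyResult", function(object) {
  cat(sprintf("AnisotropyResult: index %.3f (eigenvalues %s)\n", object@index,
              paste(signif(object@eigenvalues, 4), collapse = ", ")))
})

#' @rdname InvasionProfile-class
#' @export
setMethod("invasionDepths", "InvasionProfile", function(object) object@depths)

setMethod("show", "InvasionProfile", function(object) {
  cat(sprintf("InvasionProfile: %d cells, surface z = %.1f um, median depth %.1f um\n",
              object@nCells, object@surfaceZ, median(object@depths)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene ('%s'): %d beads in %.0f x %.0f x %.0f um box, seed %d\n",
              object@model, nrow(object@positions), object@box[1],
              object@box[2], object@box[3], object@seed))
})

#' @importFrom stats median
NULL
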