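#' @rdname ImageStack-class
#' @param object,x an object
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageStack-class
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname ImageStack-class
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname BeadSet-class
#' @param object an object with point coordinates
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname MatchedDisplacements-class
#' @param object an object
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))

#' @rdname MatchedDisplacements-class
#' @export
setGeneric("matchResiduals", function(object) standardGeneric("matchResiduals"))

#' @rdname MatchedDisplacements-class
#' @export
setGeneric("lostMask", function(object) standardGeneric("lostMask"))

#' @rdname TetMesh-class
#' @param object an object
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname TetMesh-class
#' @export
setGeneric("elements", function(object) standardGeneric("elements"))

#' @rdname TetMesh-class
#' @export
setGeneric("volumes", function(object) standardGeneric("volumes"))

#' @rdname TetMesh-class
#' @export
setGeneric("quality", function(object) standardGeneric("quality"))

#' @rdname TetMesh-class
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname StrainEnergyField-class
#' @param object an object
#' @export
setGeneric("rawEnergy", function(object) standardGeneric("rawEnergy"))

#' @rdname StrainEnergyField-class
#' @export
setGeneric("correctedEnergy", function(object) standardGeneric("correctedEnergy"))

#' @rdname StrainEnergyField-class
#' @export
setGeneric("energyDensity", function(object) standardGeneric("energyDensity"))

#' @rdname StrainEnergyField-class
#' @export
setGeneric("noiseBaselines", function(object) standardGeneric("noiseBaselines"))

#' @rdname ElasticMaterial-class
#' @param object an object
#' @export
setGeneric("shearModulus", function(object) standardGeneric("shearModulus"))

#' @rdname ElasticMaterial-class
#' @export
setGeneric("poissonRatio", function(object) standardGeneric("poissonRatio"))

#' @rdname ElasticMaterial-class
#' @export
setGeneric("lameLambda", function(object) standardGeneric("lameLambda"))

#' @rdname AnisotropyResult-class
#' @param object an object
#' @export
setGeneric("anisotropyIndex", function(object) standardGeneric("anisotropyIndex"))

#' @rdname InvasionProfile-class
#' @param object an object
#' @export
setGeneric("invasionDepths", function(object) standardGeneric("invasionDepths"))
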