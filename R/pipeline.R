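# End-to-end analysis pipeline and run configuration.

#' Run configuration
#'
#' Bundles every tunable parameter of the stack-pair analysis with the
#' reference defaults: voxel spacing (0.645, 0.645, 2.0) um, collagen
#' elasticity G = 118 Pa and nu = 0.35, displacement-noise SDs (0.022, 0.022,
#' 0.130) um, quality threshold q_min = 0.5, and the (4.5, 4.5, 14.0) um
#' matching subvolume.
#'
#' @param spacing numeric(3) voxel pitch, um.
#' @param shearModulus,poissonRatio gel elasticity (Pa, dimensionless).
#' @param noiseSigma numeric(3) displacement-noise SDs, um.
#' @param qMin tetrahedron quality threshold.
#' @param subvolumeSize numeric(3) matching subvolume, um.
#' @param searchRadius tracking search radius, um.
#' @param threshold bead detection threshold, or "auto" (half of the stack
#'   maximum).
#' @param minSeparation bead de-duplication distance, um.
#' @param driftCorrect subtract far-field median displacement.
#' @param radii integration radii for the total-energy curve, um.
#' @param center integration center (um) or NULL for the energy-weighted
#'   centroid.
#' @param seed integer seed recorded in reports.
#' @return a validated configuration list (class `tfm3dConfig`).
#' @export
runConfig <- function(spacing = c(0.645, 0.645, 2.0), shearModulus = 118,
                      poissonRatio = 0.35,
                      noiseSigma = c(0.022, 0.022, 0.130), qMin = 0.5,
                      subvolumeSize = c(4.5, 4.5, 14.0), searchRadius = 10,
                      threshold = "auto", minSeparation = 3,
                      driftCorrect = FALSE, radii = seq(20, 150, 10),
                      center = NULL, seed = 1L) {
  stopifnot(all(spacing > 0), shearModulus > 0, all(noiseSigma >= 0),
            qMin >= 0, all(subvolumeSize > 0), searchRadius > 0)
  cfg <- list(spacing = spacing, shearModulus = shearModulus,
              poissonRatio = poissonRatio, noiseSigma = noiseSigma,
              qMin = qMin, subvolumeSize = subvolumeSize,
              searchRadius = searchRadius, threshold = threshold,
              minSeparation = minSeparation, driftCorrect = driftCorrect,
              radii = radii, center = center, seed = as.integer(seed))
  class(cfg) <- "tfm3dConfig"
  cfg
}

#' Read/write a run configuration as JSON
#'
#' The serialization round-trips losslessly, so a report's embedded
#' configuration reproduces the run.
#'
#' @param config a configuration from [runConfig()].
#' @param path JSON file.
#' @return `writeConfig`: `path` invisibly; `readConfig`: the configuration.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, raw[!vapply(raw, is.null, logical(1))])
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Full stack-pair analysis
#'
#' Runs the complete workflow on a relaxed/deformed stack pair: bead
#' detection in the relaxed stack, sub-voxel tracking into the deformed
#' stack, Delaunay tessellation of the relaxed positions, shape-quality
#' filtering, per-element strain energy with noise-baseline subtraction,
#' total-energy integration, and strain-energy anisotropy. Every stage's
#' parameters and counts are recorded in the report.
#'
#' @param config a configuration from [runConfig()].
#' @param relaxed,deformed [ImageStack-class] objects or TIFF paths (read
#'   with `config$spacing`). The relaxed (force-free) stack provides the
#'   reference bead positions.
#' @param reportPath optional path; when given, the report is written there
#'   as JSON.
#' @return report list: `total_energy_pJ`, `convergence` (radii and
#'   cumulative energies), `anisotropy_index`, element/bead counts,
#'   parameters, provenance. The intermediate objects are attached in
#'   `$objects`.
#' @export
runPipeline <- function(config = runConfig(), relaxed, deformed,
                        reportPath = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) message(sprintf("[tfm3d %6.1fs] %s",
                                          proc.time()[["elapsed"]] - t0, what))
  if (is.character(relaxed)) relaxed <- readStack(relaxed, config$spacing)
  if (is.character(deformed)) deformed <- readStack(deformed, config$spacing)

  thr <- config$threshold
  if (identical(thr, "auto")) thr <- 0.5 * max(voxels(relaxed))
  stage(sprintf("detecting beads (threshold %.4g)", thr))
  beads <- detectBeads(relaxed, thr, config$minSeparation)
  if (length(beads) < 5L) stop("stage detect: fewer than 5 beads found")

  stage(sprintf("tracking %d beads", length(beads)))
  disp <- trackAll(relaxed, deformed, beads,
                   subvolumeSize = config$subvolumeSize,
                   searchRadius = config$searchRadius,
                   driftCorrect = config$driftCorrect)

  stage("tessellating")
  kept <- !lostMask(disp)
  mesh <- tessellate(positions(disp)[kept, , drop = FALSE], qMin = config$qMin)

  stage("assembling strain energy field")
  material <- ElasticMaterial(config$shearModulus, config$poissonRatio)
  noise <- NoiseModel(config$noiseSigma)
  field <- assembleField(mesh, displacements(disp)[kept, , drop = FALSE],
                         material, noise)

  aniso <- tryCatch(energyAnisotropy(field), error = function(e) NULL)
  center <- config$center
  if (is.null(center))
    center <- if (!is.null(aniso)) aniso@centroid else colMeans(nodes(mesh))
  energy <- totalEnergy(field, center, config$radii)
  stage("done")

  report <- list(
    total_energy_pJ = energy$plateau_pJ,
    convergence = list(radii_um = energy$radii_um,
                       cumulative_pJ = energy$cumulative_pJ),
    anisotropy_index = if (!is.null(aniso)) aniso@index else NA,
    center_um = as.numeric(center),
    counts = list(beads_detected = length(beads),
                  beads_lost = sum(lostMask(disp)),
                  elements_total = nrow(elements(mesh)),
                  elements_excluded = sum(!validMask(mesh)),
                  elements_filled = sum(field@filled)),
    parameters = list(G_Pa = config$shearModulus,
                      nu = config$poissonRatio,
                      noise_sigma_um = config$noiseSigma,
                      q_min = config$qMin,
                      subvolume_um = config$subvolumeSize,
                      search_radius_um = config$searchRadius,
                      spacing_um = config$spacing,
                      threshold = thr,
                      drift_corrected = config$driftCorrect,
                      seed = config$seed),
    provenance = list(software = "tfm3d",
                      version = as.character(packageVersion("tfm3d")),
                      config_md5 = .configHash(config)))
  if (!is.null(reportPath))
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report$objects <- list(beads = beads, displacements = disp, mesh = mesh,
                         field = field)
  invisible(report)
}
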