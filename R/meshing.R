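# Tetrahedral meshing of bead positions and element shape quality.

# signed volume helper, vectorized over an m x 4 element table
.tetVolumes <- function(nodes, elements, signed = FALSE) {
  a <- nodes[elements[, 1], , drop = FALSE]
  u <- nodes[elements[, 2], , drop = FALSE] - a
  v <- nodes[elements[, 3], , drop = FALSE] - a
  w <- nodes[elements[, 4], , drop = FALSE] - a
  det <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
         u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
         u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  if (signed) det / 6 else abs(det) / 6
}

.edgePairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

.shapeQualities <- function(nodes, elements) {
  V <- .tetVolumes(nodes, elements)
  sl3 <- 0
  for (r in seq_len(6)) {
    d <- nodes[elements[, .edgePairs[r, 1]], , drop = FALSE] -
         nodes[elements[, .edgePairs[r, 2]], , drop = FALSE]
    sl3 <- sl3 + rowSums(d^2)^1.5
  }
  q <- ifelse(sl3 > 0, 36 * sqrt(2) * V / sl3, 0)
  pmin(pmax(q, 0), 1)
}

#' Tetrahedron shape-quality factor
#'
#' Ratio of element volume to the sum of its six cubed edge lengths,
#' normalized by `36 * sqrt(2)` so that a regular tetrahedron scores exactly 1
#' and exactly coplanar (flat) elements score 0. The factor is invariant under
#' rotation, translation, uniform scaling and vertex permutation. Flat
#' elements amplify displacement noise into spurious strain energy and are
#' excluded below a threshold (see [filterByQuality()]).
#'
#' @param elementNodes 4 x 3 matrix of vertex coordinates (um).
#' @return shape factor q in `[0, 1]`.
#' @examples
#' reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
#' shapeQuality(reg)          # 1: regular tetrahedron
#' shapeQuality(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))  # 0: flat
#' @export
shapeQuality <- function(elementNodes) {
  elementNodes <- as.matrix(elementNodes)
  stopifnot(nrow(elementNodes) == 4L, ncol(elementNodes) == 3L)
  if (all(apply(elementNodes, 2, function(x) diff(range(x))) == 0))
    stop("all four points are identical")
  .shapeQualities(elementNodes, matrix(1:4, nrow = 1))
}

#' Delaunay tetrahedralization of bead positions
#'
#' Tessellates the (relaxed-state) bead positions into linear tetrahedral
#' finite elements via incremental Delaunay construction. Every node appears
#' in at least one element and the union of elements is the convex hull of
#' the nodes. Per-element volumes and shape-quality factors are computed and
#' the quality filter is applied (threshold `qMin`, see [filterByQuality()]).
#'
#' @param x bead positions: an n x 3 matrix (um), a [BeadSet-class], or a
#'   [MatchedDisplacements-class] (lost beads are dropped).
#' @param qMin shape-quality threshold applied to the new mesh (default 0.5).
#' @return a [TetMesh-class]
#' @examples
#' set.seed(1)
#' mesh <- tessellate(matrix(runif(60, 0, 100), ncol = 3))
#' sum(volumes(mesh))
#' @export
tessellate <- function(x, qMin = 0.5) {
  if (is(x, "BeadSet")) x <- positions(x)
  if (is(x, "MatchedDisplacements")) x <- positions(x)[!lostMask(x), , drop = FALSE]
  nodes <- as.matrix(x)
  if (ncol(nodes) != 3L) stop("nodes must be n x 3 (um)")
  if (nrow(nodes) < 5L) stop("need at least 5 nodes for a non-degenerate mesh")
  if (qr(sweep(nodes, 2, colMeans(nodes)))$rank < 3L)
    stop("nodes are coplanar or collinear; cannot tessellate")
  elements <- .cpp_delaunay(nodes)
  if (nrow(elements) == 0L) stop("tessellation is degenerate")
  storage.mode(elements) <- "integer"
  vol <- .tetVolumes(nodes, elements)
  q <- .shapeQualities(nodes, elements)
  mesh <- new("TetMesh", nodes = nodes, elements = elements, volumes = vol,
              quality = q, validMask = rep(TRUE, nrow(elements)))
  filterByQuality(mesh, qMin)
}

#' Exclude noise-amplifying flat elements
#'
#' Marks elements with shape factor `q < qMin` invalid. The default threshold
#' 0.5 rejects elements that are disproportionately sensitive to displacement
#' noise; elements scoring exactly `qMin` are kept. Nodes and elements are
#' untouched, only the validity mask changes.
#'
#' @param mesh a [TetMesh-class].
#' @param qMin quality threshold (default 0.5).
#' @return the mesh with an updated `validMask`; warns when more than half of
#'   the elements are excluded.
#' @export
filterByQuality <- function(mesh, qMin = 0.5) {
  stopifnot(is(mesh, "TetMesh"))
  mask <- mesh@quality >= qMin
  if (length(mask) > 0 && mean(mask) < 0.5)
    warning(sprintf("quality filter excluded %.0f%% of elements",
                    100 * (1 - mean(mask))))
  mesh@validMask <- mask
  mesh
}

#' Element centroids
#' @param mesh a [TetMesh-class]
#' @return m x 3 matrix of element centroids (um).
#' @export
elementCentroids <- function(mesh) {
  (mesh@nodes[mesh@elements[, 1], , drop = FALSE] +
   mesh@nodes[mesh@elements[, 2], , drop = FALSE] +
   mesh@nodes[mesh@elements[, 3], , drop = FALSE] +
   mesh@nodes[mesh@elements[, 4], , drop = FALSE]) / 4
}

#' Export a mesh as a legacy VTK unstructured grid
#'
#' Writes nodes and tetrahedra with shape quality, validity, and optional
#' per-element scalars as cell data, for visualization in ParaView.
#'
#' @param mesh a [TetMesh-class].
#' @param path output file.
#' @param cellData named list of extra per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, cellData = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh@nodes); m <- nrow(mesh@elements)
  writeLines(c("# vtk DataFile Version 3.0", "tfm3d tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  write(t(mesh@nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  write(t(cbind(4L, mesh@elements - 1L)), con, ncolumns = 5)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(10L, m), con, ncolumns = 10)
  writeLines(sprintf("CELL_DATA %d", m), con)
  allData <- c(list(quality = mesh@quality, valid = as.numeric(mesh@validMask)),
               cellData)
  for (nm in names(allData)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    write(allData[[nm]], con, ncolumns = 6)
  }
  invisible(path)
}

#' Mesh element table
#' @param mesh a [TetMesh-class]
#' @return data.frame: element_id, n0..n3, volume_um3, q, valid.
#' @export
meshElementTable <- function(mesh) {
  data.frame(element_id = seq_len(nrow(mesh@elements)),
             n0 = mesh@elements[, 1], n1 = mesh@elements[, 2],
             n2 = mesh@elements[, 3], n3 = mesh@elements[, 4],
             volume_um3 = mesh@volumes, q = mesh@quality,
             valid = mesh@validMask)
}
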