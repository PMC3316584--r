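# TIFF stack and CSV table input/output.

# natural sort: numeric runs compare numerically (so "slice2" < "slice10")
.naturalOrder <- function(x) {
  keys <- lapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    ifelse(is.na(nums), parts, sprintf("%020.0f", nums))
  })
  order(vapply(keys, paste, character(1), collapse = ""))
}

#' Read a z-stack from TIFF
#'
#' Reads either one multi-page TIFF or a numbered series of single-page files
#' (sorted naturally, so `slice2` precedes `slice10`) into an
#' [ImageStack-class]. Slices are stored in ascending z; the physical voxel
#' spacing is supplied by the caller since TIFF rarely carries it reliably.
#'
#' @param path one multi-page TIFF path, or a character vector of single-page
#'   paths.
#' @param spacing numeric(3) voxel pitch in um.
#' @param origin numeric(3) corner coordinate in um.
#' @return an [ImageStack-class]
#' @export
readStack <- function(path, spacing = c(0.645, 0.645, 2.0),
                      origin = c(0, 0, 0)) {
  readOne <- function(f) {
    p <- tiff::readTIFF(f, all = TRUE)
    if (is.array(p) && !is.list(p)) p <- list(p)
    sidecar <- paste0(f, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$intensity_scale))
        p <- lapply(p, function(page) page * meta$intensity_scale)
    }
    p
  }
  pages <- if (length(path) == 1L) readOne(path) else
    do.call(c, lapply(path[.naturalOrder(path)], readOne))
  shapes <- vapply(pages, function(p) dim(p)[1:2], numeric(2))
  if (any(shapes != shapes[, 1]))
    stop("slices have inconsistent shapes")
  # TIFF pages are [row, col] = [y, x]; stack as [x, y, z]
  vox <- vapply(pages, function(p) t(p[, , drop = TRUE][, , drop = TRUE]),
                matrix(0, shapes[2, 1], shapes[1, 1]))
  ImageStack(vox, spacing = spacing, origin = origin)
}

#' Write a z-stack as a multi-page TIFF
#'
#' Stores intensities as 32-bit float samples, one page per z-slice. TIFF
#' payloads must lie in the unit range, so intensities are divided by the next power
#' of two above the stack maximum; the scale and the voxel spacing go into a
#' JSON sidecar (`<path>.json`) that [readStack()] applies. The scaling is
#' exact in binary floating point, so a write/read round-trip reproduces
#' intensities at the precision of the 32-bit float samples.
#'
#' @param stack an [ImageStack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  mx <- max(stack@voxels, 0)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  pages <- lapply(seq_len(dim(stack@voxels)[3]),
                  function(k) t(stack@voxels[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "deflate")
  jsonlite::write_json(list(intensity_scale = scale,
                            spacing_um = stack@spacing,
                            origin_um = stack@origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write bead displacements as CSV
#'
#' Columns: bead_id, x_um, y_um, z_um, ux_um, uy_um, uz_um, residual, lost.
#'
#' @param disp a [MatchedDisplacements-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDisplacementsCSV <- function(disp, path) {
  p <- positions(disp); u <- displacements(disp)
  df <- data.frame(bead_id = seq_len(nrow(p)), x_um = p[, 1], y_um = p[, 2],
                   z_um = p[, 3], ux_um = u[, 1], uy_um = u[, 2],
                   uz_um = u[, 3], residual = matchResiduals(disp),
                   lost = lostMask(disp))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read bead displacements from CSV
#'
#' Inverse of [writeDisplacementsCSV()].
#'
#' @param path CSV file with the displacement-table columns.
#' @return a [MatchedDisplacements-class]
#' @export
readDisplacementsCSV <- function(path) {
  df <- read.csv(path)
  need <- c("x_um", "y_um", "z_um", "ux_um", "uy_um", "uz_um")
  if (!all(need %in% names(df)))
    stop("missing displacement columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lost <- if ("lost" %in% names(df)) as.logical(df$lost) else
    rep(FALSE, nrow(df))
  res <- if ("residual" %in% names(df)) as.numeric(df$residual) else
    rep(0, nrow(df))
  new("MatchedDisplacements",
      refPositions = as.matrix(df[, c("x_um", "y_um", "z_um")]),
      displacements = as.matrix(df[, c("ux_um", "uy_um", "uz_um")]),
      residuals = res, lost = lost, provenance = list(source = path))
}

#' Write or read cell contours as CSV vertex lists
#'
#' Columns: cell_id, vertex_index, x_um, y_um.
#'
#' @param contours named list of v x 2 vertex matrices (um).
#' @param path CSV file.
#' @return `writeContoursCSV`: `path`, invisibly; `readContoursCSV`: a named
#'   list of vertex matrices.
#' @export
writeContoursCSV <- function(contours, path) {
  ids <- names(contours)
  if (is.null(ids)) ids <- as.character(seq_along(contours))
  df <- do.call(rbind, lapply(seq_along(contours), function(i) {
    v <- contours[[i]]
    data.frame(cell_id = ids[i], vertex_index = seq_len(nrow(v)),
               x_um = v[, 1], y_um = v[, 2])
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContoursCSV
#' @export
readContoursCSV <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$cell_id, df$vertex_index), ]
  lapply(split(df[, c("x_um", "y_um")], df$cell_id), as.matrix)
}
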