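#' Construct a 3D volume with a voxel-to-world affine
#'
#' The basic volumetric container: a 3D numeric array plus a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in mm (RAS+). All
#' distances in this package are computed in world mm, never voxel units, so
#' anisotropic grids are handled uniformly. Per-axis voxel spacing is derived
#' from the Euclidean norms of the affine's first three columns.
#'
#' @param data 3D numeric array (all extents >= 1).
#' @param affine 4x4 invertible voxel-index-to-world-mm matrix; the default
#'   identity treats indices as mm.
#' @return An object of class `volume3d` with elements `data`, `affine`,
#'   `spacing` (mm per axis) and `dim`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), affine = diag(c(2, 2, 2, 1)))
#' v$spacing
#' @export
volume3d <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) {
    stop("`data` must have exactly 3 axes, got ", length(dim(data)))
  }
  if (any(dim(data) < 1L)) stop("all volume extents must be >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  storage.mode(affine) <- "double"
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps) {
    stop("`affine` must be invertible")
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be positive on every axis")
  storage.mode(data) <- "double"
  structure(
    list(data = data, affine = affine, spacing = spacing,
         dim = dim(data)),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat("volume3d: ", paste(x$dim, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 6), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Map continuous voxel indices to world coordinates
#'
#' Applies the volume's affine to homogeneous 0-based voxel indices. Indices
#' may be fractional and may lie outside the grid.
#'
#' @param volume A [volume3d()].
#' @param index Length-3 numeric vector or n x 3 matrix of 0-based indices.
#' @return World coordinates in mm, same shape as `index`.
#' @seealso [world_to_voxel()], [nearest_voxel()]
#' @export
voxel_to_world <- function(volume, index) {
  idx <- as_point_matrix(index)
  out <- cbind(idx, 1) %*% t(volume$affine[1:3, , drop = FALSE])
  if (is.null(dim(index))) drop(out) else out
}

#' Map world coordinates to continuous voxel indices
#'
#' Exact inverse of [voxel_to_world()]; no rounding is performed.
#'
#' @inheritParams voxel_to_world
#' @param point Length-3 numeric vector or n x 3 matrix of world mm.
#' @return Continuous 0-based voxel indices, same shape as `point`.
#' @export
world_to_voxel <- function(volume, point) {
  pts <- as_point_matrix(point)
  inv <- solve(volume$affine)
  out <- cbind(pts, 1) %*% t(inv[1:3, , drop = FALSE])
  if (is.null(dim(point))) drop(out) else out
}

#' Nearest integer voxel to a world point
#'
#' Rounds the continuous voxel index componentwise to the nearest integer.
#' Exact half-fractions round toward the LOWER index, a fixed tie-break that
#' keeps results platform-independent. A point is in bounds when every
#' rounded index lies in `[0, dim - 1]`.
#'
#' @inheritParams world_to_voxel
#' @param point Length-3 world point in mm.
#' @return List with `index` (integer 3-vector, 0-based) and `in_bounds`
#'   (logical).
#' @export
nearest_voxel <- function(volume, point) {
  cont <- world_to_voxel(volume, point)
  idx <- as.integer(ceiling(cont - 0.5))  # 0.5 rounds down
  list(index = idx,
       in_bounds = all(idx >= 0L & idx <= volume$dim - 1L))
}

# World coordinates of every voxel center, as an (prod(dim) x 3) matrix in
# R's column-major voxel order (i fastest).
voxel_center_grid <- function(volume) {
  d <- volume$dim
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  voxel_to_world(volume, idx)
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d()] whose affine is the file's stored transform.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  volume3d(as.array(img), affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 64-bit float so values round-trip bit-exactly; the
#' affine is stored in the sform (code 2).
#'
#' @param volume A [volume3d()] (or compatible mask/distance-map object).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  dat <- volume$data
  if (is.logical(dat)) {
    dat <- array(as.double(dat), dim = dim(dat))
  }
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

## ---- Contacts CSV ----------------------------------------------------------

#' Read electrode contact records
#'
#' Expects the dialect `patient_id,hemisphere,contact_index,x_mm,y_mm,z_mm`
#' with one row per contact; coordinates are world mm (RAS+). The key
#' `(patient_id, hemisphere, contact_index)` must be unique.
#'
#' @param path CSV file path.
#' @return A data.frame of contact records.
#' @export
read_contacts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "hemisphere", "contact_index",
                "x_mm", "y_mm", "z_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("contacts file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(df$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  if (any(df$contact_index < 0)) stop("contact_index must be >= 0")
  key <- paste(df$patient_id, df$hemisphere, df$contact_index)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, hemisphere, contact_index) keys in ", path)
  }
  df
}

#' Write electrode contact records
#'
#' @param contacts Data.frame with columns `patient_id`, `hemisphere`,
#'   `contact_index`, `x_mm`, `y_mm`, `z_mm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  write.csv(contacts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- Transform JSON --------------------------------------------------------

#' Read a spatial transform from JSON
#'
#' The JSON stores the 4x4 affine as nested row-major lists plus optional
#' warp parameters (see [spatial_transform()]).
#'
#' @param path JSON file path.
#' @return A [spatial_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows_to_matrix <- function(rows) {
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  warp <- obj$warp
  if (!is.null(warp)) {
    warp <- list(
      amplitudes_mm = as.numeric(unlist(warp$amplitudes_mm)),
      wavelength_mm = as.numeric(warp$wavelength_mm),
      directions = rows_to_matrix(warp$directions),
      phases = as.numeric(unlist(warp$phases))
    )
  }
  spatial_transform(rows_to_matrix(obj$affine), warp = warp)
}

#' Write a spatial transform to JSON
#'
#' @param transform A [spatial_transform()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  obj <- list(affine = apply(transform$affine, 1, as.list))
  obj$affine <- lapply(seq_len(4), function(i) as.numeric(transform$affine[i, ]))
  if (!is.null(transform$warp)) {
    w <- transform$warp
    obj$warp <- list(
      amplitudes_mm = w$amplitudes_mm,
      wavelength_mm = w$wavelength_mm,
      directions = lapply(seq_len(nrow(w$directions)),
                          function(i) as.numeric(w$directions[i, ])),
      phases = w$phases
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
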