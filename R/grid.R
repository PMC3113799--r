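#' Define a 3D voxel lattice in stereotaxic (Talairach) space
#'
#' A `volume_grid` records the geometry of the sampling lattice: the number of
#' voxels per axis, the voxel edge lengths in mm, and the Talairach mm
#' coordinate of the center of voxel (1,1,1).  Axes follow the RAS convention
#' (+x right, +y anterior, +z superior), so left-hemisphere structures have
#' negative x.
#'
#' @param dims integer(3), voxels per axis.
#' @param voxel_mm numeric(3), voxel edge lengths in mm (default 3 mm
#'   isotropic, the working resolution of the analysis).
#' @param origin_mm numeric(3), Talairach mm coordinate of the center of the
#'   first voxel.  Defaults to centering the grid on the Talairach origin.
#' @param orientation axis convention tag; only "RAS" is supported.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_mm = c(3, 3, 3), origin_mm = NULL,
                        orientation = "RAS") {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (length(voxel_mm) != 3 || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel_mm must be 3 strictly positive finite values")
  if (!identical(orientation, "RAS"))
    stop("only the RAS orientation convention is supported")
  if (is.null(origin_mm)) origin_mm <- -voxel_mm * (dims - 1) / 2
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3, all(is.finite(origin_mm)))
  structure(list(dims = dims, voxel_mm = voxel_mm, origin_mm = origin_mm,
                 orientation = orientation),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) [%s]\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3], x$orientation))
  invisible(x)
}

#' Map Talairach mm coordinates to voxel indices
#'
#' Rounds to the nearest voxel center; exact half-voxel ties round toward
#' -Inf (the lower index), so the mapping is deterministic.
#'
#' @param mm numeric(3) or an n x 3 matrix of Talairach mm coordinates.
#' @param grid a [volume_grid].
#' @param check error on out-of-bounds results (default TRUE).
#' @return integer voxel indices (1-based), same shape as the input.
#' @export
mm_to_index <- function(mm, grid, check = TRUE) {
  m <- if (is.matrix(mm)) mm else matrix(as.numeric(mm), nrow = 1)
  stopifnot(ncol(m) == 3)
  v <- sweep(sweep(m, 2, grid$origin_mm, "-"), 2, grid$voxel_mm, "/")
  # nearest with ties toward -Inf: ceiling(x - 1/2)
  idx <- ceiling(v - 0.5) + 1L
  storage.mode(idx) <- "integer"
  if (check) {
    bad <- which(idx < 1L | idx > matrix(grid$dims, nrow(idx), 3, byrow = TRUE),
                 arr.ind = TRUE)
    if (length(bad)) {
      i <- bad[1, 1]
      stop(sprintf("coordinate (%g, %g, %g) mm maps to voxel index (%d, %d, %d), outside grid %s",
                   m[i, 1], m[i, 2], m[i, 3], idx[i, 1], idx[i, 2], idx[i, 3],
                   paste(grid$dims, collapse = "x")))
    }
  }
  if (is.matrix(mm)) idx else idx[1, ]
}

#' Map voxel indices to Talairach mm coordinates (voxel centers)
#'
#' @inheritParams mm_to_index
#' @param idx integer(3) or n x 3 matrix of 1-based voxel indices.
#' @export
index_to_mm <- function(idx, grid) {
  m <- if (is.matrix(idx)) idx else matrix(as.numeric(idx), nrow = 1)
  stopifnot(ncol(m) == 3)
  mm <- sweep(sweep(m - 1, 2, grid$voxel_mm, "*"), 2, grid$origin_mm, "+")
  if (is.matrix(idx)) mm else mm[1, ]
}

index_in_bounds <- function(idx, grid) {
  m <- if (is.matrix(idx)) idx else matrix(idx, nrow = 1)
  all(m >= 1L) && all(sweep(m, 2, grid$dims, "<=") == TRUE)
}

#' In-plane voxel size implied by an acquisition matrix and field of view
#'
#' @param fov_mm field of view in mm (e.g. 192 for 19.2 cm).
#' @param matrix_size number of samples across the FOV (e.g. 64).
#' @return voxel size in mm.
#' @export
fov_voxel_size <- function(fov_mm, matrix_size) {
  stopifnot(fov_mm > 0, matrix_size >= 1)
  fov_mm / matrix_size
}

#' Volume in mm^3 of a voxel mask
#'
#' @param mask a logical array, or directly a voxel count.
#' @param grid a [volume_grid] supplying the voxel size.
#' @return total volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask, grid) {
  n <- if (is.numeric(mask) && length(mask) == 1) mask else sum(mask, na.rm = TRUE)
  n * prod(grid$voxel_mm)
}
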