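#' Seed specification
#'
#' @param name seed name.
#' @param center_mm numeric(3), Talairach mm center.
#' @return object of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mm) {
  stopifnot(length(center_mm) == 3, all(is.finite(center_mm)))
  structure(list(name = name, center_mm = as.numeric(center_mm)),
            class = "seed_spec")
}

#' Resolve a seed to its 7-voxel sphere
#'
#' The seed sphere is the voxel containing the seed center plus its 6
#' face-adjacent neighbors: the unique 7-voxel sphere on the grid, covering
#' 189 mm^3 at 3 mm isotropic resolution.
#'
#' @param seed a [seed_spec()] (or anything with `$center_mm`).
#' @param grid a [volume_grid].
#' @return integer 7 x 3 matrix of voxel indices; the first row is the
#'   center voxel.
#' @export
resolve_seed <- function(seed, grid) {
  ctr <- mm_to_index(seed$center_mm, grid)
  offs <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  vox <- sweep(offs, 2, ctr, "+")
  if (any(vox < 1) || any(sweep(vox, 2, grid$dims, ">")))
    stop(sprintf("seed '%s': a face neighbor of the center voxel falls outside the grid",
                 seed$name))
  storage.mode(vox) <- "integer"
  vox
}

#' Mean time course over a set of seed voxels
#'
#' @param run a [bold_run()].
#' @param voxels integer n x 3 matrix of voxel indices.
#' @return numeric series of length n_time (unweighted voxel mean).
#' @export
seed_timecourse <- function(run, voxels) {
  if (any(voxels < 1) || any(sweep(voxels, 2, run$grid$dims, ">")))
    stop("seed voxels out of bounds")
  flat <- flat_index(voxels, run$grid$dims)
  rowMeans(run_matrix(run, flat))
}

#' Seed correlation map over a volume of interest
#'
#' Pearson correlation of the seed time course with every in-mask voxel
#' series.  Voxels with zero temporal variance are undefined (NA) and are
#' excluded from all downstream group statistics.
#'
#' @param seed_series numeric series of length n_time.
#' @param run a [bold_run()].
#' @param mask logical 3D array (the VOI).
#' @param seed_name,subject_id metadata carried on the map.
#' @return object of class `conn_map` with `values` (3D array, NA outside the
#'   VOI and at undefined voxels), `type = "r"`, seed and subject metadata.
#' @export
correlation_map <- function(seed_series, run, mask, seed_name = "seed",
                            subject_id = run$subject_id) {
  if (length(seed_series) != n_time(run))
    stop("seed series length does not match the run")
  xs <- seed_series - mean(seed_series)
  sx <- sqrt(sum(xs^2))
  if (sx == 0) stop("zero-variance seed series")
  vox <- mask_flat(mask)
  Y <- run_matrix(run, vox)                 # T x V
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  sy <- sqrt(colSums(Yc^2))
  r <- as.numeric(crossprod(Yc, xs)) / (sy * sx)
  r[sy == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  vals <- array(NA_real_, dim(mask))
  vals[vox] <- r
  structure(list(values = vals, type = "r", seed = seed_name,
                 subject_id = subject_id, group = run$group),
            class = "conn_map")
}

#' Fisher r-to-z transform
#'
#' z = 0.5 log((1 + r) / (1 - r)), the variance-stabilizing transform applied
#' to correlation maps before averaging and group testing.
#'
#' @param r correlations in (-1, 1) (vector or array; NA passes through).
#' @param allow_infinite if TRUE, |r| = 1 maps to signed Inf instead of
#'   raising an error.
#' @return transformed values, same shape.
#' @export
fisher_z <- function(r, allow_infinite = FALSE) {
  bad <- abs(r) >= 1 & !is.na(r)
  if (any(bad) && !allow_infinite)
    stop("fisher_z: |r| >= 1; use allow_infinite = TRUE for signed infinities")
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse Fisher transform
#'
#' @param z any finite values (vector or array; NA passes through).
#' @return correlations in (-1, 1), same shape.
#' @export
fisher_z_inv <- function(z) {
  tanh(z)    # exact inverse of 0.5 log((1+r)/(1-r)), overflow-safe
}

#' Fisher-transform a correlation map
#'
#' @param rmap a `conn_map` of type "r".
#' @inheritParams fisher_z
#' @return a `conn_map` of type "z".
#' @export
z_map <- function(rmap, allow_infinite = FALSE) {
  stopifnot(inherits(rmap, "conn_map"), rmap$type == "r")
  rmap$values <- fisher_z(rmap$values, allow_infinite = allow_infinite)
  rmap$type <- "z"
  rmap
}

#' Group-average correlation map
#'
#' Averages the subjects' Fisher z maps voxelwise and applies the inverse
#' transform, so the returned map shows correlation values.  A display
#' threshold (conventionally r = 0.45) is applied only at rendering/export
#' time, never here.
#'
#' @param zmaps list of `conn_map`s of type "z" sharing seed and VOI.
#' @return a `conn_map` of type "r" (the group map).
#' @export
group_mean_rmap <- function(zmaps) {
  stopifnot(length(zmaps) >= 1)
  seed <- zmaps[[1]]$seed
  na0 <- is.na(zmaps[[1]]$values)
  for (m in zmaps) {
    stopifnot(inherits(m, "conn_map"), m$type == "z")
    if (!identical(m$seed, seed)) stop("z maps mix different seeds")
    if (!identical(dim(m$values), dim(zmaps[[1]]$values)))
      stop("z maps have mismatched masks")
  }
  stack <- vapply(zmaps, function(m) m$values, zmaps[[1]]$values)
  dim(stack) <- c(length(zmaps[[1]]$values), length(zmaps))
  mz <- rowMeans(stack, na.rm = TRUE)
  mz[rowSums(!is.na(stack)) == 0] <- NA_real_
  vals <- array(fisher_z_inv(mz), dim(zmaps[[1]]$values))
  structure(list(values = vals, type = "r", seed = seed,
                 subject_id = NA_character_, group = "group-mean"),
            class = "conn_map")
}

#' Apply a display threshold to a group correlation map
#'
#' @param map a `conn_map` of type "r".
#' @param threshold display threshold (default 0.45); values with |r| below
#'   it are set to NA.
#' @return the thresholded map.
#' @export
threshold_map <- function(map, threshold = 0.45) {
  stopifnot(inherits(map, "conn_map"))
  map$values[abs(map$values) < threshold] <- NA_real_
  map
}
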