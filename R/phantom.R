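#' Build a phantom volume of interest from spherical regions
#'
#' Constructs a binary VOI mask as the union of spherical regions and an
#' integer label map assigning every VOI voxel to the region that claimed it
#' first.  A voxel belongs to a sphere when the sphere intersects the voxel's
#' cube, so a radius smaller than half a voxel still yields the single center
#' voxel, and a radius of half a voxel edge picks up exactly the center voxel
#' plus its 6 face neighbors (7 voxels, 189 mm^3 on a 3 mm grid).
#'
#' @param grid a [volume_grid].
#' @param regions data.frame with columns `name`, `x`, `y`, `z` (Talairach mm)
#'   and `radius_mm`.
#' @return list with `mask` (logical 3D array), `labels` (integer 3D array,
#'   0 outside), `region_names` (character, label i = region_names[i]),
#'   `regions` (the input table) and `grid`.
#' @export
make_phantom_voi <- function(grid, regions) {
  stopifnot(is.data.frame(regions),
            all(c("name", "x", "y", "z", "radius_mm") %in% names(regions)))
  mask <- array(FALSE, grid$dims)
  labels <- array(0L, grid$dims)
  half <- grid$voxel_mm / 2
  for (i in seq_len(nrow(regions))) {
    ctr <- as.numeric(regions[i, c("x", "y", "z")])
    r <- regions$radius_mm[i]
    if (r < 0) stop(sprintf("region '%s': negative radius", regions$name[i]))
    cidx <- tryCatch(mm_to_index(ctr, grid),
                     error = function(e)
                       stop(sprintf("region '%s': center out of grid bounds (%s)",
                                    regions$name[i], conditionMessage(e))))
    # candidate index window around the sphere
    lo <- ceiling((ctr - r - grid$origin_mm - half) / grid$voxel_mm) + 1
    hi <- floor((ctr + r - grid$origin_mm + half) / grid$voxel_mm) + 1
    vox <- sphere_voxels(ctr, r, grid, lo, hi)
    if (any(vox < 1) || any(sweep(vox, 2, grid$dims, ">")))
      stop(sprintf("region '%s' does not fit inside the grid bounds", regions$name[i]))
    flat <- vox[, 1] + grid$dims[1] * (vox[, 2] - 1L) +
      grid$dims[1] * grid$dims[2] * (vox[, 3] - 1L)
    mask[flat] <- TRUE
    unclaimed <- flat[labels[flat] == 0L]
    labels[unclaimed] <- i
  }
  list(mask = mask, labels = labels, region_names = as.character(regions$name),
       regions = regions, grid = grid)
}

# voxels whose cube intersects the sphere (center ctr mm, radius r mm);
# search window [lo, hi] in index space, which may poke outside the grid --
# bounds are checked by the caller so out-of-grid spheres raise errors.
sphere_voxels <- function(ctr, r, grid, lo, hi) {
  half <- grid$voxel_mm / 2
  ax <- lapply(1:3, function(a) seq(lo[a], hi[a]))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  centers <- sweep(sweep(g - 1, 2, grid$voxel_mm, "*"), 2, grid$origin_mm, "+")
  d <- abs(sweep(centers, 2, ctr, "-"))
  d <- sweep(d, 2, half, "-")
  d[d < 0] <- 0
  keep <- sqrt(rowSums(d^2)) <= r + 1e-9
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Voxel indices of a phantom region
#'
#' @param phantom result of [make_phantom_voi()].
#' @param name region name.
#' @return integer matrix of voxel indices (n x 3).
#' @export
region_voxels <- function(phantom, name) {
  i <- match(name, phantom$region_names)
  if (is.na(i)) stop(sprintf("unknown region '%s'", name))
  which(phantom$labels == i, arr.ind = TRUE)
}

#' Default full-scale phantom emulating the perisylvian language VOI
#'
#' Eight mirrored spherical regions on a 3 mm Talairach grid: left/right
#' inferior frontal (BA44 and IFS), left/right posterior superior temporal
#' (pSTS) and bilateral precentral (PCG) regions, with the left-hemisphere
#' seed regions centered on the canonical language-network seed coordinates
#' BA44 (-53, 20, 15), IFS (-47, 20, 30) and STS (-56, -43, 9).
#'
#' @param radius_mm region sphere radius in mm (default 7.5).
#' @return A phantom list as returned by [make_phantom_voi()].
#' @export
default_phantom <- function(radius_mm = 7.5) {
  grid <- volume_grid(c(44, 50, 40), c(3, 3, 3), origin_mm = c(-66, -75, -45))
  regions <- data.frame(
    name = c("L_BA44", "R_BA44", "L_IFS", "R_IFS",
             "L_pSTS", "R_pSTS", "L_PCG", "R_PCG"),
    x = c(-53, 53, -47, 47, -56, 56, -48, 48),
    y = c(20, 20, 20, 20, -43, -43, -6, -6),
    z = c(15, 15, 30, 30, 9, 9, 15, 15),
    radius_mm = radius_mm,
    stringsAsFactors = FALSE)
  make_phantom_voi(grid, regions)
}

#' The three canonical seed definitions
#'
#' Seed 1 in left BA44, seed 2 in left IFS, seed 3 in left STS, each resolved
#' downstream to the 7-voxel face-neighbor sphere (189 mm^3 at 3 mm).
#'
#' @return data.frame with columns name, x, y, z (Talairach mm).
#' @export
default_seeds <- function() {
  data.frame(name = c("BA44", "IFS", "STS"),
             x = c(-53, -47, -56), y = c(20, 20, -43), z = c(15, 30, 9),
             stringsAsFactors = FALSE)
}

#' Desk-scale phantom with the same left/right topology
#'
#' A reduced lattice carrying six mirrored regions (left/right frontal,
#' left/right posterior temporal, bilateral precentral) used by the
#' simulation-validation experiments and the demo configuration.  Region
#' classes mirror the full phantom so the group coupling topologies (adult:
#' left frontal to left posterior temporal; child: interhemispheric temporal
#' and bilateral precentral) can be planted unchanged.
#'
#' @param radius_mm region sphere radius in mm (default 6).
#' @return A phantom list as returned by [make_phantom_voi()].
#' @export
mini_phantom <- function(radius_mm = 6) {
  grid <- volume_grid(c(24, 26, 22), c(3, 3, 3),
                      origin_mm = c(-34.5, -37.5, -31.5))
  regions <- data.frame(
    name = c("LF", "RF", "LT", "RT", "LP", "RP"),
    x = c(-21, 21, -21, 21, -15, 15),
    y = c(15, 15, -18, -18, 0, 0),
    z = c(6, 6, 3, 3, 18, 18),
    radius_mm = radius_mm,
    stringsAsFactors = FALSE)
  make_phantom_voi(grid, regions)
}

#' Minimal two-region phantom for null-calibration experiments
#'
#' @param radius_mm region sphere radius in mm (default 12).
#' @return A phantom list as returned by [make_phantom_voi()].
#' @export
null_phantom <- function(radius_mm = 12) {
  grid <- volume_grid(c(20, 18, 16), c(3, 3, 3),
                      origin_mm = c(-28.5, -25.5, -22.5))
  regions <- data.frame(
    name = c("L", "R"),
    x = c(-12, 12), y = c(0, 0), z = c(0, 0),
    radius_mm = radius_mm,
    stringsAsFactors = FALSE)
  make_phantom_voi(grid, regions)
}
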