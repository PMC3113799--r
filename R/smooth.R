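#' Spatial Gaussian smoothing of a 4D run
#'
#' Each volume is convolved with a separable isotropic Gaussian of the given
#' full width at half maximum (sigma = FWHM / (2 sqrt(2 log 2)) in mm,
#' converted to voxels per axis).  Boundaries are handled by half-sample
#' reflection, which preserves the spatial mean of each volume.
#' `fwhm_mm = 0` is the identity.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm smoothing kernel FWHM in mm (default 4).
#' @return the smoothed [bold_run()].
#' @export
smooth_spatial <- function(run, fwhm_mm = 4) {
  run$data <- smooth_array(run$data, run$grid, fwhm_mm)
  attr(run, "smoothing_fwhm_mm") <- fwhm_mm
  run
}

#' Gaussian-smooth a 3D or 4D array on a grid
#'
#' Backend for [smooth_spatial()] and for the Monte Carlo null simulations.
#'
#' @param x 3D or 4D numeric array (spatial dims first).
#' @param grid a [volume_grid] supplying voxel sizes.
#' @param fwhm_mm kernel FWHM in mm; 0 returns `x` unchanged.
#' @return array of the same shape.
#' @export
smooth_array <- function(x, grid, fwhm_mm) {
  if (length(fwhm_mm) != 1 || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single nonnegative number")
  if (fwhm_mm == 0) return(x)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_mm
  d <- dim(x)
  if (!(length(d) %in% c(3, 4)) || !all(d[1:3] == grid$dims))
    stop("x must be a 3D or 4D array matching the grid dims")
  gauss_smooth_cpp(x, as.integer(d), sigma_vox)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))
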