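#' Write a BOLD run as 4D NIfTI-1
#'
#' Voxel sizes go into the header pixdims and the TR into the 4th pixdim.
#'
#' @param run a [bold_run()].
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  arr <- run$data
  attr(arr, "pixdim") <- c(run$grid$voxel_mm, run$TR)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read a 4D NIfTI-1 run
#'
#' @param path NIfTI file.
#' @param grid a [volume_grid] describing the lattice (NIfTI carries voxel
#'   sizes but not the Talairach origin convention used here); voxel sizes
#'   are cross-checked against the header.
#' @param subject_id,group metadata for the returned run.
#' @param TR if NULL, taken from the header's 4th pixdim.
#' @return a [bold_run()].
#' @export
read_bold_nifti <- function(path, grid, subject_id = basename(path),
                            group = NA_character_, TR = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  hdr <- RNifti::niftiHeader(img)
  if (is.null(TR)) TR <- hdr$pixdim[5]
  vx <- hdr$pixdim[2:4]
  if (any(abs(vx - grid$voxel_mm) > 1e-4))
    warning(sprintf("header voxel size (%s) differs from grid (%s)",
                    paste(signif(vx, 4), collapse = "x"),
                    paste(grid$voxel_mm, collapse = "x")))
  bold_run(arr, TR, grid, subject_id = subject_id, group = group)
}

#' Write a 3D mask or label volume as NIfTI-1
#'
#' @param vol logical or integer 3D array.
#' @param grid a [volume_grid].
#' @param path output file.
#' @export
write_mask_nifti <- function(vol, grid, path) {
  arr <- array(as.integer(vol), dim(vol))
  attr(arr, "pixdim") <- grid$voxel_mm
  attr(arr, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

#' Read a 3D NIfTI volume as an integer array
#'
#' @param path NIfTI file.
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 3) arr <- arr[, , , 1]
  arr
}

#' Write a connectivity or statistic map as NIfTI-1
#'
#' Undefined voxels (NA) are written as NaN.
#'
#' @param map a `conn_map` or `stat_map`.
#' @param grid a [volume_grid].
#' @param path output file.
#' @export
write_map_nifti <- function(map, grid, path) {
  arr <- map$values
  attr(arr, "pixdim") <- grid$voxel_mm
  attr(arr, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read / write event tables
#'
#' Tab-separated with columns onset_s, duration_s, condition.
#'
#' @param events data.frame of events.
#' @param path file path.
#' @name events_io
NULL

#' @rdname events_io
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname events_io
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "duration_s", "condition") %in% names(ev)))
  ev
}

#' Read a study manifest written by [simulate_study()]
#'
#' @param path manifest.json path.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
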