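#' Construct a BOLD run
#'
#' A `bold_run` bundles one subject's 4D time series with its acquisition
#' metadata.  The data array follows the NIfTI layout: dimensions
#' (x, y, z, t), with time as the fourth axis.
#'
#' @param data 4D numeric array, dims = c(grid$dims, n_time).
#' @param TR repetition time, seconds.
#' @param grid a [volume_grid].
#' @param subject_id character subject identifier.
#' @param group group label (e.g. "adults", "children").
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, TR, grid, subject_id = "subj", group = NA_character_) {
  d <- dim(data)
  if (length(d) != 4 || !all(d[1:3] == grid$dims))
    stop("data must be a 4D array matching the grid dims")
  if (d[4] < 2) stop("a run needs at least 2 time steps")
  if (TR <= 0) stop("TR must be positive")
  structure(list(data = data, TR = TR, grid = grid,
                 subject_id = subject_id, group = group),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run '%s' (%s): %d x %d x %d voxels x %d time steps, TR %g s\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4], x$TR))
  invisible(x)
}

n_time <- function(run) dim(run$data)[4]

# T x V matrix view of (a subset of) the run's voxel series
run_matrix <- function(run, voxels = NULL) {
  d <- dim(run$data)
  V <- prod(d[1:3])
  M <- matrix(run$data, V, d[4])
  if (!is.null(voxels)) M <- M[voxels, , drop = FALSE]
  t(M)
}

# flat indices of TRUE voxels of a 3D logical mask
mask_flat <- function(mask) which(as.logical(mask))

flat_index <- function(idx, dims) {
  m <- if (is.matrix(idx)) idx else matrix(idx, nrow = 1)
  m[, 1] + dims[1] * (m[, 2] - 1L) + dims[1] * dims[2] * (m[, 3] - 1L)
}
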